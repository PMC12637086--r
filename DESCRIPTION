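Package: tmedyn
Title: Temporal Dynamics of the Tumor Microenvironment from Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for longitudinal single-cell analysis of the
    tumor microenvironment: recursive hierarchical cell typing (per-node
    signal-to-noise gene selection, centered unscaled PCA, graph-community
    clustering, density filtering, marker annotation), simplex/archetype
    analysis with a permutation t-ratio test, CRISPR-screen-weighted
    single-cell fitness scores, phenotype discretization and temporal
    prevalence/density summaries, mode-scaled multiplexed-imaging cell typing,
    weighted cross-species composition analysis, preranked gene-set
    enrichment, and a synthetic-data generator with planted ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
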