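# tmedyn

Temporal dynamics of the tumor microenvironment (TME) from longitudinal
single-cell data.

`tmedyn` is an R package for analysts studying how the cellular composition
and the phenotypes of a tumor — cancer cells, macrophages/monocytes,
T cells, dendritic cells, stroma — change over time from serial scRNA-seq
samples, with orthogonal validation from multiplexed immunofluorescence and
genome-wide CRISPR screens. It implements, as tested and reusable
functions:

* **Recursive hierarchical cell typing.** At every level: selection of
  genes with signal-to-noise ratio SNR > 0.25 (SD of denoised expression
  across cells relative to the mean sampling error), centered unscaled PCA
  with an automated elbow rule, Leiden community detection on a k = 20
  shared-nearest-neighbor graph under a resolution schedule
  (0.02 / 0.03 / 0.07 / 0.1 by depth), a low-RNA filter
  (log UMI < median − 3 MAD) and an isolation filter on the statistic
  *n·d³* (d = mean distance to the k nearest neighbors), and marker-based
  cluster annotation that reports ties instead of guessing.
* **Simplex / archetype analysis.** Cells of one type are modeled as
  convex combinations of k = d + 1 archetypes in d PCs
  (x<sub>c</sub> ≈ Σ<sub>a</sub> w<sub>ca</sub> A<sub>a</sub>, w ≥ 0,
  Σw = 1). The fitter is a soft minimum-volume simplex (SISAL/MVSA
  family). Significance comes from the **t-ratio** — the volume of the
  minimal enclosing fitted simplex over the volume of the data's convex
  hull, both exact — compared against 1000 datasets whose PC columns are
  independently shuffled: p = (1 + #{t<sub>b</sub> ≤ t<sub>obs</sub>}) /
  (1 + B).
* **CRISPR-weighted fitness of single cells.** score<sub>c</sub> =
  Σ<sub>g</sub> LTQ<sub>gc</sub> · NormZ<sub>g</sub>, joined by gene id,
  with a Wilcoxon rank-sum comparison of the 5% of cells closest to a
  phenotype archetype against the rest.
* **Phenotype dynamics.** Discretization rules (PC sign, PC1 > 0 & PC2 > 0,
  single-gene LTQ threshold −7.7; 25% closest to each archetype, 20%
  closest to the origin as generalists), prevalence normalized to all
  cells sequenced per timepoint, prevalence-scaled 1D phenotype densities,
  caliper tumor volume V = (1/6)·π·L·l², and classification of prevalence
  series into stable colonization / wave-like / progressive increase.
* **Imaging-based cell typing.** Scaling of each fluorescence channel by
  the highest-intensity mode of its log1p distribution, searched within
  gated (parent-positive) cells for rare markers; Leiden clustering on the
  first two PCs with k = max(round(n·10⁻³), 10); necessary/possible marker
  annotation; log-scale composition comparison against scRNA-seq.
* **Cross-species composition.** Species-wise centered log compositions,
  PCA weighted by inverse species sample counts (e.g. 1/8 mouse, 1/26
  human), and pseudo-bulk TPM (UMI fraction × 10⁶).
* **A synthetic-data generator** that plants all of the above — Poisson
  counts around cell-scaled log rates, a simplex continuum, a 1D
  trajectory, three temporal patterns, bimodal gated marker channels,
  signature-enriched NormZ tables — with ground truth, so every stage is
  testable without external data.

The denoised expression scale throughout is the **LTQ** (log transcription
quotient): a shrunken natural-log estimate of each gene's fraction of a
cell's transcriptome, with a per-gene sampling-error bar (see the methods
vignette for the estimator).

## Worked example

Simulate a noisy population on a known 3D simplex, fit four archetypes,
and test the simplex against the shuffled null:

```r
library(tmedyn)

arch <- matrix(c(0,0,0, 4,0,0, 0,4,0, 0,0,4), 4, 3, byrow = TRUE)
pop  <- simulate_simplex_population(2000, arch,
                                    noise_sd = 0.05 * max(dist(arch)),
                                    concentration = 0.8, seed = 7)
fit  <- fit_simplex(pop$x, n_archetypes = 4, n_restarts = 5, seed = 7)
fit
#> simplex_fit: 4 archetypes in 3 dims, 2000 cells
#> t-ratio: 0.3411  enclosed: FALSE  objective: 4.789

tt <- t_ratio_test(pop$x, 4, n_shuffles = 200, seed = 7)
tt$t_ratio ; tt$p_value
#> [1] 2.211041
#> [1] 0.004975124
```

The fitted archetypes land within a few percent of the planted vertices
(`fit$archetypes`), and each cell's `fit$weights` row gives its barycentric
position on the simplex. The robust fit prints the volume ratio of its own
(non-enclosing) simplex; the significance test refits in enclosure mode,
and that t-ratio of 2.21 is smaller than in every one of the 200 shuffled
datasets
(tighter fit than any correlation-free null), giving the minimum attainable
p of 1/201 ≈ 0.005 — the data are simplex-shaped beyond what the marginal
PC distributions explain.

The full chain — simulation, QC, LTQ estimation, hierarchical typing,
archetypes, fitness, dynamics, imaging, cross-species — runs from one
configuration:

```r
manifest <- run_pipeline(default_pipeline_config(seed = 1), "out/")
```

and records per-stage seeds, output digests and filter counts in
`out/manifest.json`.

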