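---
title: "Methods: models, parameters and design choices in tmedyn"
author: "tmedyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in tmedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmedyn)
```

# Scope

`tmedyn` implements the computational backbone of a longitudinal single-cell
study of the breast-tumor microenvironment: recursive hierarchical cell
typing from denoised single-cell expression, simplex (archetype) analysis of
phenotypic continua with a permutation significance test, CRISPR-screen
weighted per-cell fitness scores, phenotype discretization and temporal
prevalence summaries, cell typing from multiplexed immunofluorescence
intensity tables, and cross-species composition comparison. Every stage can
be exercised on synthetic data with planted ground truth, generated by the
package itself.

This vignette explains the models behind each stage, the tunable parameters
with their defaults and units, the numerical choices, and the limits of what
the synthetic tests demonstrate.

# The synthetic-data generator

`simulate_counts()` draws UMI counts as
$n_{gc} \sim \mathrm{Poisson}(s_c \, \rho_{gc})$ where
$\rho_{\cdot c}$ is the cell's expression profile,
$\exp(\lambda_{gc})$ normalized to sum to one over genes, and
$s_c$ is a log-normal size factor with mean `depth` (default study
configurations use 2\,000–6\,000 UMIs per cell, log-scale SD 0.3). Poisson
sampling noise is the premise of the normalization model below, so the
generator matches it by construction; a negative-binomial switch
(`nb_size`) adds overdispersion for robustness experiments and is off by
default because the study's normalization model assumes Poisson noise.

Within one cell type, three kinds of planted structure are available:

* **Simplex continuum** — each cell's log-rate vector is a convex
  combination of archetype profiles with Dirichlet-distributed weights.
  The Dirichlet concentration defaults to 0.8, which enriches cells near
  the corners of the simplex, matching the non-uniform occupancy seen in
  real tumor-associated macrophage/monocyte data.
* **1D trajectory** — a latent position in $[-1, 1]$ times a gene loading
  vector.
* **Temporal pattern** — per-type relative abundance over timepoints
  follows one of three shapes: *stable colonization* (a rise from the first
  timepoint, then constant), *wave-like* (an interior peak), or
  *progressive increase* (monotone growth; the default profile doubles per
  timepoint). Per-timepoint type fractions are normalized to sum to one
  and cells are apportioned by largest remainder.

Two percent of genes carry the reserved `mt-` prefix so the mitochondrial
QC filter is exercisable. All randomness flows from a single seed;
submodules derive child seeds deterministically (`derive_seed()`), so
changing one stage's seed never perturbs another stage.

The generator emulates Poisson sampling, log-normal depth variation,
marker-block cell identities and smooth within-type continua. It does not
emulate ambient RNA, doublets, batch effects, gene–gene correlation beyond
the planted programs, or the $\sim$20k-gene scale of real data (defaults
are desk-scale, a few hundred genes). Passing tests therefore demonstrate
algorithmic correctness under the stated noise model, not robustness to
every artifact of real experiments.

# Quality control and LTQ estimation

`qc_filter()` removes genes detected in fewer than 5 cells, then cells with
fewer than 100 detected genes, then cells with more than 12.5% mitochondrial
UMIs. The order genes → cells → mito is fixed and documented so the filter
is reproducible and idempotent; the mitochondrial cutoff is applied globally
by default with a per-sample switch.

`estimate_ltq()` estimates each gene's **log transcription quotient**
(LTQ): the natural-log fraction of a cell's transcriptome attributable to
the gene, denoised for Poisson sampling. It is an empirical-Bayes Gaussian
shrinkage estimator with a documented closed form: with plug-in frequency
$y_{gc} = \log\{(n_{gc}+p)/(N_c+2p)\}$ (pseudocount $p = 0.5$), per-entry
sampling variance $v_{gc} \approx 1/(n_{gc}+p)$, pooled log fraction
$\mu_g$ and moment-matched prior variance
$\hat\sigma_g^2 = \max\{\widehat{\mathrm{var}}(y_{g\cdot}) - \bar v_g,\,
0\}$, the estimate is

$$\mathrm{LTQ}_{gc} = \mu_g + w_g\,(y_{gc}-\mu_g), \qquad
  w_g = \frac{\hat\sigma_g^2}{\hat\sigma_g^2 + 1/(\bar n_g + p)}.$$

Two numerical choices matter. First, the shrinkage weight is **per gene**,
not per cell: cell-wise weights make shallow cells systematically closer to
the pooled mean, which manifests as a spurious "sequencing depth" principal
component that can dominate downstream geometry. Second, the weight's
denominator uses the sampling variance at the gene's *mean* expression, so
deep coverage always drives $w_g \to 1$ and the estimator converges to the
plug-in log frequency. The reported per-gene error bar is the mean log-scale
sampling SD, $\overline{\sqrt{v_{g\cdot}}}$ — the noise magnitude the
estimator filters out. This estimator satisfies the contract of the study's
normalization tool (denoised LTQs plus per-gene error bars); no claim of
numerical equivalence with that tool's full Bayesian inference is made.

The **SNR gene filter** keeps genes whose biological signal, the SD of LTQ
across cells, exceeds 0.25 times their mean sampling error. Genes with zero
error and positive signal are kept (infinite SNR). The **low-RNA filter**
finds the lower tail of UMI content as log-total below median − 3 MAD; a
zero MAD (all depths equal) removes nothing. Both are re-applied inside
every node of the typing hierarchy, because what counts as "low RNA" or
"informative gene" is cell-type specific.

# Hierarchical cell typing

Each node of the typing tree runs, in order: the low-RNA filter, SNR gene
selection, centered unscaled PCA (exact SVD; the sign of each loading
column is fixed so its largest-magnitude entry is positive), the elbow rule,
Leiden graph clustering, the isolation filter, marker annotation, and
recursion into each cluster.

* **Elbow rule.** The number of PCs is the index starting the most convex
  triple of the scree curve — the argmax over $i$ of
  $v_i - 2v_{i+1} + v_{i+2}$ — bounded to $[2, n_{max}]$. A curve with no
  elbow (e.g. geometric decay) returns the lower bound. The study chose
  PCs by visual elbow; this is the automated equivalent.
* **Clustering.** A $k$-nearest-neighbor graph ($k = 20$, Euclidean in PC
  space) with shared-nearest-neighbor Jaccard edge weights (edges below
  1/15 pruned), partitioned by Leiden modularity maximization. Leiden was
  chosen over Louvain as a strict quality improvement with the same
  resolution semantics; the run is seeded and bitwise reproducible. The
  resolution schedule follows the study: 0.02 at the top level, 0.03 for
  homogeneous sub-populations, 0.07 to split T helper from cytotoxic T
  cells, 0.1 for dendritic-cell subsets; entries are indexed by tree depth
  with the last value recycled.
* **Isolation filter.** For each cell, $d$ is the mean distance to its
  $k$ nearest neighbors. At constant density $d^3 \propto 1/n$, so
  $n d^3$ is comparable across clusters of different sizes; cells above a
  cutoff sit in low-density regions with uncertain assignments. The study
  set the cutoff by visual inspection; the default here is the node's 95th
  percentile of $n d^3$, exposed as configuration.
* **Annotation.** Each cluster scores each candidate type by the mean,
  over the type's markers, of cluster-mean LTQ z-scored across clusters;
  the best type wins only if it beats the runner-up by 0.5 z-units,
  otherwise the cluster is `"unresolved"` — ties are surfaced, never
  guessed.
* **Stopping.** Recursion ends when Leiden returns a single community at
  the node's scheduled resolution (the node is flagged as a continuum at
  that granularity — the study's judgment-based "cells formed a continuum"
  rule made operational) or when a node falls below `min_cells`.

# Simplex / archetype analysis

Cells of one type are projected on their first $d$ PCs and modeled as
convex combinations of $k = d + 1$ archetypes (the study: $d = 3$,
$k = 4$). Two fitting modes serve two different questions.

**Robust mode** (default; `lambda = 30`) answers *where are the
archetypes?* It minimizes $\log \mathrm{vol}(V) + \frac{\lambda}{n}
\sum_{i,j} \max(0, -b_{ij})$ over vertex matrices $V$, where $b_{ij}$ are
barycentric coordinates — a soft minimum-volume simplex in the SISAL/MVSA
family, optimized by BFGS with analytic gradients from furthest-point
initializations inflated to enclose the data. The linear hinge lets a few
noise-displaced cells sit slightly outside rather than dragging vertices
outward, which is what makes archetype positions recoverable to within a
few percent of the simplex diameter at realistic noise; a hard enclosing
fit is dominated by the most extreme noise excursions and biases vertices
outward by several times that. If, after fitting, full enclosure needs
less than 2% homothetic inflation, the fit snaps to it — in the noiseless
limit this returns the exact simplex. Replicated identical points equal in
number to the archetypes are returned as the vertices themselves. Weights
are barycentric coordinates clipped at zero and renormalized.

**Enclosure mode** (`enclose = TRUE`, `lambda = 2000`) answers *does a
simplex describe the data?* The **t-ratio** is the volume of the fitted
simplex divided by the volume of the data's convex hull, both exact; for
the comparison to be meaningful the simplex must enclose the data, so this
mode always inflates the fitted simplex to the minimal enclosing homothety,
making the t-ratio $\ge 1$, with values near 1 meaning the data fill a
simplex. Hull volumes are computed exactly in 1D (range), 2D (hull polygon
shoelace) and 3D (quickhull); dimensions above 3 are refused — the study
only needs 3D, and no exact higher-dimensional hull backend is available.
Fits with more archetypes than $d+1$ (the study's 5- and 6-archetype
robustness checks) use a principal-convex-hull alternating
projected-gradient fit with archetypes constrained to the data hull; they
support enrichment comparisons, not the hull-based t-ratio.

`t_ratio_test()` shuffles each PC column independently across cells —
preserving each coordinate's marginal distribution, destroying their
correlation — and refits (enclosure mode) on each of `n_shuffles = 1000`
shuffled datasets with the identical procedure. Small t-ratios mean tight
fits, so $p = (1 + \#\{t_b \le t_{obs}\}) / (1 + B)$, with add-one
smoothing giving a minimum attainable $p$ of $1/(B+1)$; fewer than 19
shuffles triggers a warning because the floor then exceeds 0.05. Because
the robust-mode vertices and the enclosure-mode test use different
hinge weights, the reported archetype positions are not the simplex whose
volume enters the test; this mirrors the study's tooling, where
archetype-finding algorithms and the t-ratio's enclosing simplex are also
distinct constructions.

**Discretization.** Each archetype's candidate set is the 25% of cells
closest to it; a cell claimed by two archetypes goes to the nearer one,
and the 20% of cells closest to the origin of PC space are labeled
*generalist*, overriding archetype labels (the study is silent on
conflicts; generalist-wins plus nearest-archetype is our documented,
configurable rule). **Enrichment** near each archetype uses a two-sided
Wilcoxon rank-sum test of the closest-set against all other cells, per
gene or per mean-LTQ pathway score, with Benjamini–Hochberg q-values
within archetype. The study's tooling uses a bin-based enrichment
procedure; equivalence is not claimed.

**Continuum diagnostic.** A kernel density estimate over the first two PCs
(grid 80×80; per-axis Gaussian SD bandwidth, normal-reference default)
yields local maxima and their widths as the FWHM of each peak's half-max
region. The per-gene sampling errors are propagated through the loadings
to an error SD per PC, expressed as the FWHM a pure-noise cluster would
show; if every peak is no wider than 1.5× that (the factor absorbs KDE
bandwidth widening), the data are consistent with discrete clusters
blurred by measurement error, otherwise they support a genuine continuum.

# Fitness scores from CRISPR screens

Per-cell fitness is the dot product of the cell's LTQs with per-gene NormZ
scores from a knockout screen under cytotoxic-T-cell selection, joined by
gene id: $\mathrm{score}_c = \sum_g \mathrm{LTQ}_{gc}\,\mathrm{NormZ}_g$.
LTQs enter on their natural-log scale as-is, matching the study's formula
literally; `center_genes = TRUE` subtracts gene means first, since the
study is ambiguous about centering. The symbol-based join is reported
(intersection size attached to the result); ortholog mapping is out of
scope. `archetype_fitness_test()` compares the 5% of cells closest to a
target archetype against the rest with a two-sided Wilcoxon rank-sum test
and reports which group is higher; groups smaller than 3 cells are
refused.

# Phenotype dynamics

Discretization rules follow the study, with boundary conventions made
explicit: sign-of-PC splits send exact zeros to "positive"; the cytotoxic/
proliferative T-cell quadrant requires strictly positive PC1 and PC2; the
IFN-response split of cancer cells thresholds one gene's LTQ at −7.7 with
ties going to "high". Prevalence is normalized by **all** cells sequenced
at the timepoint (not by the cell type's own count), with an explicit
"unlabeled" row so fractions sum to one. 1D phenotype densities are scaled
so the area under each timepoint's curve equals the type's prevalence
then. Caliper tumor volume is $V = \frac{1}{6}\pi L l^2$.

`classify_temporal_pattern()` names the three patterns with artifact-defined
rules (the study names the patterns but gives no formula): series are
normalized by their maximum (scale invariance); *stable colonization* =
later points at least 2× the initial value with CV ≤ 0.25; *progressive
increase* = monotone non-decreasing with final ≥ 2× initial; *wave-like* =
an interior maximum ≥ 1.5× both endpoints; otherwise "other". Stable
colonization is tested first because its rise-then-plateau shape is also
monotone.

# Multiplexed-imaging cell typing

Because fluorescence channels differ in brightness and dynamic range, and
log intensities are bimodal with very different positive fractions,
channels are scaled by the location of the **highest-intensity** (rightmost)
mode of the log1p intensities — not the tallest mode, which for a rare
marker is the negative population. After scaling, negative cells sit near
0 and positive populations center at 1. For rare markers the mode search is
gated: the positive mode of a child marker (e.g. a T-cell marker) is
searched only among parent-positive cells (scaled parent > 0.5), in
topological order of the gating graph. Modes need at least 5% of the
tallest peak's height to qualify (rare ungated populations fall below
this — the quantitative reason gating is necessary); a detected mode below
0.5 log-units means the channel has no real positive population, and the
channel is scaled by that floor instead and flagged. `log1p` rather than
`log` handles zero intensities after background subtraction. The 0.5
positivity cutoff is the midpoint between the two scaled populations — the
study does not state its cutoff; ours is documented and configurable.

Cells expressing at least one marker are clustered by Leiden (resolution 1)
on the first two PCs of the scaled signals with
$k = \max(\mathrm{round}(n \times 10^{-3}), 10)$ neighbors. Clusters are
annotated by necessary/possible marker rules: a cluster matches a type iff
every necessary marker is positive (cluster median scaled value > 0.5) and
no marker outside the necessary-or-possible set is positive; zero or
multiple matches yield `"undetermined"` with a warning. Cell-type
proportions are compared with the scRNA-seq composition on log scale
(Pearson r), with absent types floored at half the minimum nonzero
fraction and flagged.

# Cross-species composition and pseudo-bulk

Compositions (samples × cell types, rows summing to 1) are
log-transformed — so abundant types do not dominate — and column-centered
within each species separately, removing sample-independent cross-species
differences. The joint PCA weights each sample by the inverse of its
species' sample count (1/8 per mouse, 1/26 per human for the study's
design), computed as eigenvectors of
$\sum_s w_s x_s x_s^\top / \sum_s w_s$; duplicating samples while halving
their weights leaves the components unchanged. Zero fractions are floored
at half the minimum nonzero value and flagged. Pseudo-bulk "TPM" sums UMIs
per sample and scales each gene's fraction to a library of one million —
no gene-length correction, since UMI counts are molecule-level; the name
is kept with this caveat.

# Preranked gene-set enrichment

Genes are ranked by the sum of squared loadings over the leading PCs (the
strength of their expression gradient; the study reads the top 30 in the
literature), with per-PC signed loadings available for directional
analysis. The enrichment score is the classic weighted Kolmogorov–Smirnov
statistic (weight exponent 1); the null redraws each set's genes at random
(gene-label permutation, matching preranked semantics), p-values are
add-one-smoothed and sign-matched, NES divides by the mean |null ES| of
the matching sign, and q-values are Benjamini–Hochberg. Bit-compatibility
with reference implementations' adaptive p-value algorithms is not
claimed, but the enrichment score itself is checked against one in the
test suite.

# Orchestration

`run_pipeline()` chains simulate → QC → normalize → type → archetypes →
fitness → dynamics → imaging → cross-species on a single configuration
list (or YAML file) in which every study constant is a named default —
SNR 0.25, k = 20, resolutions 0.02/0.03/0.07/0.1, mito 12.5%, threshold
−7.7, 25%/20% discretization, 5% fitness comparison, 1000 shuffles. It
writes each stage's outputs plus a manifest with the configuration hash,
per-stage derived seeds, file digests and filter-removal counts; a failing
stage halts the run and the partial manifest names it. Identical
configurations reproduce identical digests, and stage seeds are isolated.

# Problem sizes and numerical tolerances

The packaged tests run at desk scale, chosen so the full suite completes
on one CPU in well under half an hour: simplex recovery and the fitness
pipeline at 2\,000 cells; the t-ratio null calibration at 50 repetitions ×
99 shuffles on 200-cell datasets with single-restart fits (the test is
calibrated as long as observed and shuffled data get the identical
procedure); typing at 3\,000 cells and nine planted types; imaging at
5\,000 cells and six types. Key tolerances: barycentric weight row sums to
1 within 1e−6; PCA loadings orthonormal within 1e−8; hull volumes exact up
to floating point; KDE-based mode locations asserted within 0.1 log-units.

# Known limitations

* The LTQ estimator is a deliberately simple stand-in for full Bayesian
  inference of transcription activity; per-gene (rather than per-cell)
  shrinkage trades some statistical efficiency for geometric cleanliness.
* The t-ratio is only available in up to 3 dimensions.
* Robust-mode archetype fits do not enclose the data, so their own
  volume ratio can fall below 1; significance always comes from
  enclosure-mode fits.
* The isolation filter's $n d^3$ scaling argument assumes 3D PC spaces;
  in other dimensions the statistic remains usable but its
  size-invariance argument weakens.
* Pattern classification rules (2× rise, 1.5× peak, CV ≤ 0.25) are
  artifact-defined conventions, not study-stated values.
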