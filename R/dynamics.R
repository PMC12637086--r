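## Phenotype discretization rules, temporal prevalence and density
## summaries, the caliper volume formula, and temporal-pattern calling.

#' Discretize cells by the sign of one PC
#'
#' Cells scoring positively (including exactly zero, by convention) on the
#' chosen PC are "positive", the rest "negative". Used for cell types whose
#' time-associated heterogeneity lies along a single PC.
#'
#' @param scores cells x d matrix of PC scores.
#' @param pc_index which PC to use.
#' @return character labels.
#' @export
discretize_pc_sign <- function(scores, pc_index = 1) {
  s <- as.matrix(scores)[, pc_index]
  stats::setNames(ifelse(s >= 0, "positive", "negative"),
                  rownames(as.matrix(scores)))
}

#' Discretize cytotoxic T cells by the PC1/PC2 quadrant
#'
#' Cells with strictly positive PC1 and PC2 are labeled
#' \code{"cytotoxic_proliferative"}; all others (including the boundary)
#' are \code{"other"}.
#'
#' @param scores cells x >=2 matrix of PC scores.
#' @return character labels.
#' @export
discretize_tc <- function(scores) {
  s <- as.matrix(scores)
  stats::setNames(ifelse(s[, 1] > 0 & s[, 2] > 0,
                         "cytotoxic_proliferative", "other"), rownames(s))
}

#' Discretize cells by a single-gene LTQ threshold
#'
#' Splits a bimodal gene into high/low populations at a fixed LTQ value;
#' the default −7.7 is the threshold that best separates the two H2-K1
#' (IFN-response) sub-populations of cancer cells. Values exactly at the
#' threshold are "high".
#'
#' @param ltq_gene per-cell LTQ values of one gene.
#' @param threshold LTQ cutoff (default -7.7).
#' @return character labels "high"/"low".
#' @export
discretize_threshold <- function(ltq_gene, threshold = -7.7) {
  stats::setNames(ifelse(ltq_gene >= threshold, "high", "low"),
                  names(ltq_gene))
}

#' Phenotype prevalence over time
#'
#' Fraction of each phenotype among ALL cells sequenced at each timepoint
#' (not among the phenotype's own cell type), so that changes in phenotype
#' prevalence and in cell type prevalence are commensurable. Cells at a
#' timepoint that carry no label are reported as "unlabeled"; fractions at
#' each timepoint (including "unlabeled") sum to 1.
#'
#' @param phenotypes data.frame(cell_id, phenotype, timepoint).
#' @param totals_per_timepoint named vector: total cells sequenced per
#'   timepoint (defaults to the labeled counts, i.e. assumes the table
#'   covers every sequenced cell).
#' @return data.frame(timepoint, phenotype, n, fraction), one row per
#'   timepoint x phenotype, zero rows retained.
#' @export
prevalence_over_time <- function(phenotypes, totals_per_timepoint = NULL) {
  .assert(all(c("phenotype", "timepoint") %in% names(phenotypes)),
          "phenotypes needs phenotype and timepoint columns")
  tp <- sort(unique(phenotypes$timepoint))
  if (is.null(totals_per_timepoint)) {
    totals_per_timepoint <- table(phenotypes$timepoint)
  }
  tot <- stats::setNames(as.numeric(totals_per_timepoint),
                         names(totals_per_timepoint))
  .assert(all(as.character(tp) %in% names(tot)),
          "totals_per_timepoint must cover every timepoint")
  phe <- sort(unique(phenotypes$phenotype))
  grid <- expand.grid(timepoint = tp, phenotype = phe,
                      stringsAsFactors = FALSE)
  cnt <- table(phenotypes$timepoint, phenotypes$phenotype)
  grid$n <- mapply(function(t, p) {
    if (as.character(t) %in% rownames(cnt) && p %in% colnames(cnt))
      cnt[as.character(t), p] else 0
  }, grid$timepoint, grid$phenotype)
  grid$fraction <- grid$n / tot[as.character(grid$timepoint)]
  ## account for sequenced-but-unlabeled cells so fractions sum to 1
  lab_n <- tapply(grid$n, grid$timepoint, sum)
  unl <- data.frame(timepoint = tp, phenotype = "unlabeled",
                    n = tot[as.character(tp)] - as.numeric(lab_n[as.character(tp)]))
  unl$fraction <- unl$n / tot[as.character(tp)]
  out <- rbind(grid, unl[unl$n > 0 | TRUE, ])
  out <- out[order(out$timepoint, out$phenotype), ]
  rownames(out) <- NULL
  out
}

#' Prevalence-scaled phenotype density along a 1D axis
#'
#' Kernel density of a cell type's 1D phenotype scores at each timepoint,
#' scaled so the area under each curve equals the cell type's prevalence
#' (cells of the type / all cells sequenced) at that timepoint. Curves are
#' evaluated on a common grid; a timepoint with no cells gets a flat zero
#' curve.
#'
#' @param scores_1d per-cell 1D scores (cells of one type).
#' @param timepoints per-cell timepoints, aligned with \code{scores_1d}.
#' @param totals_per_timepoint named vector: ALL cells sequenced per
#'   timepoint.
#' @param bandwidth KDE bandwidth (default \code{stats::bw.nrd0} of all
#'   scores).
#' @param n_grid grid size (default 512).
#' @return data.frame(timepoint, x, density); per timepoint,
#'   \code{sum(density)*dx} equals the type's prevalence.
#' @export
phenotype_density <- function(scores_1d, timepoints, totals_per_timepoint,
                              bandwidth = NULL, n_grid = 512) {
  .assert(length(scores_1d) == length(timepoints),
          "scores and timepoints must align")
  tot <- stats::setNames(as.numeric(totals_per_timepoint),
                         names(totals_per_timepoint))
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(scores_1d)
  rng <- range(scores_1d) + c(-3, 3) * bandwidth
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  out <- list()
  for (t in names(tot)) {
    s <- scores_1d[as.character(timepoints) == t]
    dens <- if (length(s) >= 2) {
      d <- stats::density(s, bw = bandwidth, from = rng[1], to = rng[2],
                          n = n_grid)
      d$y * length(s) / tot[t]
    } else if (length(s) == 1) {
      stats::dnorm(grid, s, bandwidth) / tot[t]
    } else rep(0, n_grid)
    out[[t]] <- data.frame(timepoint = t, x = grid, density = dens)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tumor volume from caliper length and width
#'
#' The ellipsoid approximation \eqn{V = \frac{1}{6}\pi L l^2} with L the
#' long axis and l the short axis.
#'
#' @param L long-axis length.
#' @param l short-axis length.
#' @return volume in the cubed input unit.
#' @export
caliper_volume <- function(L, l) pi / 6 * L * l^2

#' Classify a temporal prevalence series into one of three patterns
#'
#' Rules (scale-invariant, evaluated on the series normalized by its
#' maximum): \emph{progressive_increase} — monotone non-decreasing with a
#' total rise of at least \code{rise_factor} times the initial value;
#' \emph{wave_like} — an interior maximum exceeding both endpoints by
#' \code{peak_factor}; \emph{stable_colonization} — a rise from the first
#' timepoint after which the series stays flat (coefficient of variation of
#' the later points at most \code{cv_max}); anything else is "other".
#'
#' @param series numeric prevalence series over ordered timepoints.
#' @param rise_factor minimum final/initial ratio for a progressive
#'   increase (default 2).
#' @param peak_factor minimum peak/endpoint ratio for a wave (default 1.5).
#' @param cv_max maximum CV of post-colonization points (default 0.25).
#' @return one of "stable_colonization", "wave_like",
#'   "progressive_increase", "other".
#' @export
classify_temporal_pattern <- function(series, rise_factor = 2,
                                      peak_factor = 1.5, cv_max = 0.25) {
  x <- as.numeric(series)
  .assert(length(x) >= 3, "need at least 3 timepoints")
  .assert(all(x >= 0), "prevalences must be non-negative")
  if (max(x) == 0) return("other")
  x <- x / max(x)  # invariant to uniform rescaling
  eps <- 1e-12
  later <- x[-1]
  ## stable colonization subsumes "monotone" series that rise once then
  ## plateau, so it is checked before progressive increase
  cv <- stats::sd(later) / mean(later)
  if (mean(later) >= rise_factor * x[1] && cv <= cv_max)
    return("stable_colonization")
  if (all(diff(x) >= -eps) && x[length(x)] >= rise_factor * x[1])
    return("progressive_increase")
  pk <- which.max(x)
  if (pk > 1 && pk < length(x) &&
      x[pk] >= peak_factor * x[1] && x[pk] >= peak_factor * x[length(x)])
    return("wave_like")
  "other"
}
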