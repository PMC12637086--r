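## Quality control and a simplified log-transcription-quotient estimator.

#' Gene and cell quality filters for a UMI count matrix
#'
#' Removes, in this order: genes detected in fewer than \code{min_cells_per_gene}
#' cells; cells with fewer than \code{min_genes_per_cell} detected genes;
#' cells whose mitochondrial transcript fraction exceeds \code{mito_frac_max}.
#' Mitochondrial genes are recognized by an id prefix. The fixed
#' genes-cells-mito order makes the filter reproducible and idempotent.
#'
#' @param cm a [count_matrix()].
#' @param min_cells_per_gene keep genes detected in at least this many cells
#'   (default 5; "detected" means count > 0).
#' @param min_genes_per_cell keep cells with at least this many detected
#'   genes (default 100).
#' @param mito_frac_max maximum mitochondrial UMI fraction per cell
#'   (default 0.125); cells strictly above are removed.
#' @param mito_prefix gene-id prefix marking mitochondrial genes
#'   (default \code{"mt-"}).
#' @param per_sample if TRUE, apply the mitochondrial cutoff within each
#'   sample separately (default FALSE: global).
#' @return the filtered [count_matrix()], with a \code{qc_report} attribute
#'   listing counts removed at each step.
#' @export
qc_filter <- function(cm, min_cells_per_gene = 5, min_genes_per_cell = 100,
                      mito_frac_max = 0.125, mito_prefix = "mt-",
                      per_sample = FALSE) {
  .assert(inherits(cm, "count_matrix"), "cm must be a count_matrix")
  x <- cm$counts
  detected <- x > 0
  keep_g <- Matrix::rowSums(detected) >= min_cells_per_gene
  x <- x[keep_g, , drop = FALSE]
  keep_c1 <- Matrix::colSums(x > 0) >= min_genes_per_cell
  x <- x[, keep_c1, drop = FALSE]
  is_mito <- startsWith(rownames(x), mito_prefix)
  tot <- Matrix::colSums(x)
  mito_frac <- if (any(is_mito))
    Matrix::colSums(x[is_mito, , drop = FALSE]) / pmax(tot, 1) else
    rep(0, ncol(x))
  keep_c2 <- mito_frac <= mito_frac_max  # strictly above the cutoff removed
  x <- x[, keep_c2, drop = FALSE]
  if (ncol(x) == 0) .fail("QC removed every cell; relax the filters")
  report <- list(genes_removed_low_detection = sum(!keep_g),
                 cells_removed_few_genes = sum(!keep_c1),
                 cells_removed_mito = sum(!keep_c2),
                 genes_kept = nrow(x), cells_kept = ncol(x))
  meta <- cm$cell_meta[cm$cell_meta$cell_id %in% colnames(x), , drop = FALSE]
  out <- count_matrix(x, meta)
  attr(out, "qc_report") <- report
  out
}

#' Estimate log transcription quotients (LTQs) with per-gene error bars
#'
#' A simplified empirical-Bayes estimator of each gene's log fraction of a
#' cell's transcriptome, filtering Poisson sampling noise: the plug-in log
#' frequency \eqn{y_{gc} = \log((n_{gc}+p)/(N_c+2p))} with sampling variance
#' \eqn{v_{gc} \approx 1/(n_{gc}+p)} is shrunk toward the gene's pooled log
#' fraction under a gene-wise Gaussian prior whose variance is estimated by
#' moment matching, \eqn{\hat\sigma_g^2 = \max(\mathrm{var}(y_g) -
#' \overline{v_g}, 0)}. The shrinkage weight
#' \eqn{w_g = \hat\sigma_g^2 / (\hat\sigma_g^2 + \overline{v_g})} is
#' per-gene (not per-cell), so sequencing-depth differences between cells
#' cannot masquerade as a phenotypic axis. The gene's error bar is its mean
#' sampling error across cells, \eqn{\overline{\sqrt{v_g}}}, the log-scale
#' Poisson noise the estimator filters out.
#'
#' @param cm a QC-filtered [count_matrix()].
#' @param pseudocount_prior pseudocount p in the plug-in frequency
#'   (default 0.5).
#' @return an [ltq_matrix()].
#' @export
estimate_ltq <- function(cm, pseudocount_prior = 0.5) {
  .assert(inherits(cm, "count_matrix"), "cm must be a count_matrix")
  n <- as.matrix(cm$counts)
  N <- colSums(n)
  if (any(N == 0)) .fail("zero-total cell found; run qc_filter first")
  p <- pseudocount_prior
  y <- log(sweep(n + p, 2, N + 2 * p, "/"))
  v <- 1 / (n + p)
  mu <- log((rowSums(n) + p) / (sum(N) + 2 * p))  # pooled log fraction
  s2 <- pmax(apply(y, 1, stats::var) - rowMeans(v), 0)
  ## shrinkage uses the sampling variance at the gene's mean expression,
  ## so deep coverage always drives the weight to 1 (plug-in limit)
  vg <- 1 / (rowMeans(n) + p)
  w <- s2 / (s2 + vg)          # per-gene shrinkage toward the observation
  ltq <- mu + w * sweep(y, 1, mu)
  gene_error <- rowMeans(sqrt(v))  # mean log-scale sampling error per gene
  dimnames(ltq) <- dimnames(n)
  ltq_matrix(ltq, gene_error)
}

#' Select genes by signal-to-noise ratio
#'
#' Keeps genes whose biological signal (SD of LTQ across cells) is large
#' relative to their mean sampling error. Genes with zero error but positive
#' signal have infinite SNR and are kept.
#'
#' @param lm an [ltq_matrix()].
#' @param threshold SNR cutoff (default 0.25); genes with SNR strictly above
#'   it are kept.
#' @return character vector of retained gene ids.
#' @export
snr_genes <- function(lm, threshold = 0.25) {
  .assert(inherits(lm, "ltq_matrix"), "lm must be an ltq_matrix")
  s <- apply(lm$ltq, 1, stats::sd)
  snr <- ifelse(lm$gene_error == 0, ifelse(s > 0, Inf, 0),
                s / lm$gene_error)
  rownames(lm$ltq)[snr > threshold]
}

#' Flag low-RNA cells within a cell group
#'
#' Finds the lower tail of per-cell UMI content: cells whose log total UMI
#' falls below median − \code{mad_k}·MAD are flagged. Because RNA content is
#' cell-type specific, this is meant to be re-applied within every node of
#' the typing hierarchy. If the MAD is zero (all depths equal) no cell is
#' removed.
#'
#' @param totals per-cell total UMI counts (or a [count_matrix()], in which
#'   case column sums are used).
#' @param mad_k number of MADs below the median (default 3).
#' @return logical keep-mask, TRUE for cells passing the filter.
#' @export
low_rna_filter <- function(totals, mad_k = 3) {
  if (inherits(totals, "count_matrix")) totals <- Matrix::colSums(totals$counts)
  lt <- log(pmax(as.numeric(totals), 1))
  m <- stats::median(lt); s <- .mad(lt)
  if (s == 0) return(rep(TRUE, length(lt)))
  lt >= m - mad_k * s
}
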