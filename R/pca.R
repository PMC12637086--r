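## Centered unscaled PCA and the automated elbow rule.

#' Centered unscaled PCA of an LTQ submatrix
#'
#' Exact SVD-based principal component analysis on gene-centered, unscaled
#' log expression: cells are observations, genes are variables. Loadings
#' columns are orthonormal; the sign convention makes each column's
#' largest-magnitude entry positive so results are reproducible across
#' SVD backends.
#'
#' @param x genes x cells numeric matrix (e.g. \code{lm$ltq[genes, cells]}),
#'   or an [ltq_matrix()].
#' @param center center each gene (default TRUE).
#' @param scale scale each gene to unit variance (default FALSE, i.e.
#'   unscaled).
#' @param n_pcs_max maximum number of PCs to return (default 20).
#' @return list of class \code{pca_projection}: \code{scores}
#'   (cells x n_pcs), \code{loadings} (genes x n_pcs),
#'   \code{variance_explained} (percent, non-increasing), \code{center}.
#' @export
run_pca <- function(x, center = TRUE, scale = FALSE, n_pcs_max = 20) {
  if (inherits(x, "ltq_matrix")) x <- x$ltq
  m <- t(as.matrix(x))  # cells x genes
  m <- scale(m, center = center, scale = scale)
  ctr <- if (center) attr(m, "scaled:center") else rep(0, ncol(m))
  k <- min(n_pcs_max, nrow(m) - 1L, ncol(m))
  .assert(k >= 1, "need at least 2 cells and 1 gene")
  sv <- svd(m, nu = k, nv = k)
  ## sign convention: largest-|entry| of each loading column positive
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]; sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
  ev <- sv$d^2 / max(nrow(m) - 1L, 1L)
  ve <- 100 * ev[seq_len(k)] / sum(ev)
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve, center = ctr),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("pca_projection: %d cells x %d PCs\n",
              nrow(x$scores), ncol(x$scores)))
  cat("variance explained (%):",
      paste(sprintf("%.1f", utils::head(x$variance_explained, 8)),
            collapse = " "), "\n")
  invisible(x)
}

#' Automated elbow rule for the number of PCs
#'
#' Returns the PC index at which the scree curve bends most sharply: the
#' argmax of the second difference of the variance-explained sequence,
#' bounded to \code{[2, n_pcs_max]}. A curve with no convex elbow (e.g.
#' geometric decay, whose second difference is maximal at the start)
#' returns the lower bound.
#'
#' @param variance_explained non-increasing numeric vector (any scale).
#' @param n_pcs_max upper bound (default \code{length(variance_explained)}).
#' @return integer number of PCs.
#' @export
choose_n_pcs <- function(variance_explained,
                         n_pcs_max = length(variance_explained)) {
  v <- as.numeric(variance_explained)
  if (length(v) < 3) return(max(2L, min(length(v), n_pcs_max)))
  d2 <- v[seq_len(length(v) - 2L)] - 2 * v[seq(2L, length(v) - 1L)] +
    v[seq(3L, length(v))]
  elbow <- which.max(d2)  # first point of the most convex triple
  as.integer(min(max(elbow, 2L), n_pcs_max))
}
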