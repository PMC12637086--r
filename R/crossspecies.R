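## Cross-species composition analysis: species-wise centering of
## log-transformed compositions, inverse-sample-count weighted PCA, and
## pseudo-bulk TPM for gene-dynamics comparison.

#' Log-transform and center compositions within each species
#'
#' Fractional abundances are log-transformed (to avoid over-weighting
#' abundant cell types) and column-centered separately within each species
#' block, removing sample-independent cross-species differences in immune
#' composition. Zero fractions get a pseudo-fraction floor (half the
#' minimum nonzero fraction unless given) and are flagged.
#'
#' @param comp samples x cell-types matrix of fractions (rows sum to 1).
#' @param species character vector, one per sample.
#' @param zero_floor pseudo-fraction for zeros (default: half the minimum
#'   nonzero fraction in the table).
#' @return centered log-composition matrix, with attributes
#'   \code{floored} (logical matrix) and \code{species}.
#' @export
log_center_by_species <- function(comp, species, zero_floor = NULL) {
  comp <- as.matrix(comp)
  .assert(nrow(comp) == length(species), "one species per sample")
  .assert(all(comp >= 0), "fractions must be non-negative")
  .assert(all(abs(rowSums(comp) - 1) < 1e-6), "rows must sum to 1")
  floored <- comp == 0
  if (any(floored)) {
    if (is.null(zero_floor)) zero_floor <- min(comp[comp > 0]) / 2
    comp[floored] <- zero_floor
  }
  lg <- log(comp)
  for (sp in unique(species)) {
    rows <- species == sp
    lg[rows, ] <- scale(lg[rows, , drop = FALSE], center = TRUE,
                        scale = FALSE)
  }
  attr(lg, "floored") <- floored
  attr(lg, "species") <- species
  lg
}

#' PCA with per-sample weights
#'
#' Principal components of the weighted covariance
#' \eqn{\Sigma = \sum_s w_s x_s x_s^T / \sum_s w_s}. With weights
#' \eqn{1/n_{species}} per sample, both species contribute equally to the
#' components regardless of how many samples each has.
#'
#' @param x samples x variables centered matrix (e.g. from
#'   [log_center_by_species()]).
#' @param weights per-sample weights; alternatively use
#'   [species_weights()].
#' @return a \code{pca_projection}: scores (samples x PCs), loadings,
#'   variance explained (percent of weighted variance), eigenvalues.
#' @export
weighted_pca <- function(x, weights) {
  x <- as.matrix(x)
  .assert(length(weights) == nrow(x), "one weight per sample")
  .assert(all(weights > 0), "weights must be positive")
  w <- weights / sum(weights)
  cov_w <- crossprod(x * sqrt(w))          # sum_s w_s x_s x_s^T
  eig <- eigen(cov_w, symmetric = TRUE)
  k <- sum(eig$values > max(eig$values) * 1e-12)
  loadings <- eig$vectors[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- loadings[, j]; sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- x %*% loadings
  rownames(loadings) <- colnames(x)
  rownames(scores) <- rownames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = 100 * eig$values[seq_len(k)] /
                   sum(eig$values),
                 eigenvalues = eig$values[seq_len(k)],
                 weights = weights),
            class = "pca_projection")
}

#' Inverse-sample-count species weights
#'
#' Each sample is weighted by 1 over the number of samples of its species
#' (e.g. 1/8 per mouse and 1/26 per human for 8 mouse and 26 human
#' samples).
#'
#' @param species character vector, one entry per sample.
#' @return numeric weights, one per sample.
#' @export
species_weights <- function(species) {
  n <- table(species)
  as.numeric(1 / n[species])
}

#' Pseudo-bulk TPM from single-cell counts
#'
#' Sums UMIs over the cells of each sample and normalizes each gene's
#' fraction of the summed library to one million. (No gene-length
#' correction: for UMI counts "TPM" here means UMI fraction x 1e6.)
#'
#' @param cm a [count_matrix()].
#' @param group name of the cell_meta column to aggregate by
#'   (default "sample").
#' @return genes x groups matrix; columns sum to 1e6.
#' @export
pseudobulk_tpm <- function(cm, group = "sample") {
  .assert(inherits(cm, "count_matrix"), "cm must be a count_matrix")
  .assert(group %in% names(cm$cell_meta), "unknown grouping column %s", group)
  g <- as.character(cm$cell_meta[[group]])
  out <- vapply(unique(g), function(s)
    Matrix::rowSums(cm$counts[, g == s, drop = FALSE]),
    numeric(nrow(cm$counts)))
  out <- matrix(out, nrow = nrow(cm$counts),
                dimnames = list(rownames(cm$counts), unique(g)))
  tot <- colSums(out)
  if (any(tot == 0)) .fail("sample with zero total UMIs: %s",
                           paste(colnames(out)[tot == 0], collapse = ", "))
  sweep(out, 2, tot, "/") * 1e6
}
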