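## Per-cell fitness from CRISPR-screen gene effects: fitness = LTQ . NormZ,
## and the archetype-proximity rank-sum comparison.

#' Score single-cell fitness from CRISPR-screen NormZ effects
#'
#' Each cell's fitness is the dot product of its LTQs with the screen's
#' per-gene NormZ scores over the shared gene universe (id-based join):
#' \eqn{score_c = \sum_g ltq_{gc} \cdot normz_g}. LTQs are used on their
#' natural-log scale as-is; set \code{center_genes = TRUE} to subtract each
#' gene's mean LTQ first, which makes scores relative to the average cell.
#'
#' @param lm an [ltq_matrix()] (or plain genes x cells matrix).
#' @param normz data.frame(gene, normz); duplicate gene ids are rejected.
#' @param center_genes subtract per-gene mean LTQ first (default FALSE).
#' @return named numeric vector of per-cell fitness scores, with the size
#'   of the gene-universe intersection as attribute \code{n_genes_used}.
#' @export
fitness_scores <- function(lm, normz, center_genes = FALSE) {
  ltq <- if (inherits(lm, "ltq_matrix")) lm$ltq else as.matrix(lm)
  .assert(all(c("gene", "normz") %in% names(normz)),
          "normz needs gene and normz columns")
  .assert(!anyDuplicated(normz$gene), "duplicate gene ids in NormZ table")
  .assert(all(is.finite(normz$normz)), "NormZ values must be finite")
  shared <- intersect(rownames(ltq), normz$gene)
  if (!length(shared)) .fail("no genes shared between LTQ matrix and NormZ table")
  x <- ltq[shared, , drop = FALSE]
  if (center_genes) x <- x - rowMeans(x)
  z <- normz$normz[match(shared, normz$gene)]
  s <- as.vector(crossprod(x, z))
  names(s) <- colnames(ltq)
  attr(s, "n_genes_used") <- length(shared)
  s
}

#' Compare fitness of cells closest to an archetype vs the rest
#'
#' Two-sided Wilcoxon rank-sum test of the \code{frac} cells closest to the
#' target archetype against all remaining cells, reporting which group has
#' the higher fitness.
#'
#' @param scores per-cell fitness scores.
#' @param distances per-cell distance to the target archetype.
#' @param frac fraction defining the "closest" group (default 0.05).
#' @return list(statistic, p_value, direction, n_closest); direction is
#'   \code{"closest_higher"} or \code{"closest_lower"}.
#' @export
archetype_fitness_test <- function(scores, distances, frac = 0.05) {
  .assert(length(scores) == length(distances),
          "scores and distances must align")
  n <- length(scores)
  m <- round(frac * n)
  if (m < 3) .fail("closest group would have %d cells; increase n or frac", m)
  close_idx <- order(distances)[seq_len(m)]
  member <- seq_len(n) %in% close_idx
  wt <- stats::wilcox.test(scores[member], scores[!member], exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = if (stats::median(scores[member]) >=
                       stats::median(scores[!member]))
         "closest_higher" else "closest_lower",
       n_closest = m)
}
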