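## Preranked gene-set enrichment against PC loadings: gene ranking by
## squared loadings, and a classic weighted Kolmogorov-Smirnov enrichment
## score with a gene-label permutation null.

#' Read a GMT gene-set file
#'
#' @param path GMT file (tab-separated: name, description, genes...).
#' @return named list of deduplicated gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  .assert(all(lengths(sets) > 0), "GMT contains an empty set")
  .assert(!anyDuplicated(names(sets)), "duplicate set names in GMT")
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, n, sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Rank genes by their expression gradient on the first PCs
#'
#' Scores each gene by the sum of squares of its loadings over the selected
#' PCs — the strength of its expression gradient in the retained phenotypic
#' space — and returns genes in descending order. Per-PC signed loadings
#' are kept alongside for directional enrichment.
#'
#' @param loadings genes x PCs loading matrix (or a \code{pca_projection}).
#' @param n_pcs_for_gradient how many leading PCs to aggregate (default 3).
#' @param top optional: keep only the strongest \code{top} genes (e.g. 30
#'   for literature annotation).
#' @return data.frame(gene, score, then one signed column per selected PC),
#'   sorted by decreasing score.
#' @export
rank_genes_by_pc <- function(loadings, n_pcs_for_gradient = 3, top = NULL) {
  if (inherits(loadings, "pca_projection")) loadings <- loadings$loadings
  k <- min(n_pcs_for_gradient, ncol(loadings))
  L <- loadings[, seq_len(k), drop = FALSE]
  score <- rowSums(L^2)
  o <- order(score, decreasing = TRUE)
  out <- data.frame(gene = rownames(loadings)[o], score = score[o],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(L[o, , drop = FALSE]))
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

## weighted KS enrichment score (classic GSEA statistic, weight exponent 1)
.gsea_es <- function(stats_sorted, in_set) {
  nr <- sum(abs(stats_sorted[in_set]))
  n <- length(stats_sorted)
  nh <- sum(in_set)
  if (nh == 0 || nh == n) return(0)
  if (nr == 0) {  # all-zero in-set stats: uniform hit steps
    p_hit <- cumsum(in_set) / nh
  } else {
    p_hit <- cumsum(ifelse(in_set, abs(stats_sorted), 0)) / nr
  }
  p_miss <- cumsum(!in_set) / (n - nh)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment score (weight exponent 1)
#' of each set against a ranked gene list, with a gene-label permutation
#' null: the set's genes are redrawn at random \code{n_perm} times,
#' p-values are the add-one-smoothed two-tailed permutation fractions,
#' NES is ES divided by the mean |null ES| of the matching sign, and
#' Benjamini-Hochberg q-values are computed across sets. Sets with no gene
#' in the ranked universe are dropped with a warning.
#'
#' @param scores named numeric vector: ranking statistic per gene (sorted
#'   internally, decreasing).
#' @param sets named list of gene-id vectors.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame(set, size, ES, NES, p, q).
#' @export
preranked_gsea <- function(scores, sets, n_perm = 1000, seed = 1) {
  .assert(!is.null(names(scores)), "scores must be named by gene")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  genes <- names(s)
  keep <- vapply(sets, function(g) any(g %in% genes), TRUE)
  if (any(!keep))
    warning(sprintf("%d set(s) share no gene with the ranking; dropped",
                    sum(!keep)))
  sets <- sets[keep]
  if (!length(sets))
    return(data.frame(set = character(), size = integer(), ES = numeric(),
                      NES = numeric(), p = numeric(), q = numeric()))
  set.seed(seed)
  n <- length(genes)
  res <- lapply(names(sets), function(nm) {
    in_set <- genes %in% sets[[nm]]
    sz <- sum(in_set)
    es <- .gsea_es(s, in_set)
    null_es <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n, sz)
      m <- logical(n); m[idx] <- TRUE
      .gsea_es(s, m)
    }, numeric(1))
    side <- if (es >= 0) null_es >= 0 else null_es <= 0
    denom <- mean(abs(null_es[side]))
    nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
    p <- (1 + sum(side & abs(null_es) >= abs(es))) / (1 + sum(side))
    data.frame(set = nm, size = sz, ES = es, NES = nes, p = p)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
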