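## Recursive cell typing: graph-community clustering on PC scores, density
## (isolation) filtering, marker-based annotation, and the recursion driver.

## blocked kNN on rows of `x`: returns n x k matrix of neighbor indices
.knn_indices <- function(x, k, block = 512L) {
  n <- nrow(x)
  .assert(k < n, "k_neighbors must be smaller than the number of cells")
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  sq <- rowSums(x^2)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(x[s:e, , drop = FALSE], x)
    d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf  # drop self
    for (i in seq_len(e - s + 1L)) {
      o <- order(d2[i, ])[seq_len(k)]
      idx[s + i - 1L, ] <- o
      dst[s + i - 1L, ] <- sqrt(pmax(d2[i, o], 0))
    }
  }
  list(index = idx, dist = dst)
}

## shared-nearest-neighbor graph with Jaccard edge weights
.snn_graph <- function(knn_idx, prune = 1 / 15) {
  n <- nrow(knn_idx); k <- ncol(knn_idx)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(knn_idx),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)        # counts of shared neighbors
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j              # upper triangle, no self-loops
  i <- shared@i[keep] + 1L; j <- shared@j[keep] + 1L; s <- shared@x[keep]
  jac <- s / (2 * k - s)
  keep2 <- jac >= prune
  g <- igraph::graph_from_edgelist(cbind(i[keep2], j[keep2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- jac[keep2]
  g
}

#' Graph-community clustering of cells in PC space
#'
#' Builds a k-nearest-neighbor graph on PC scores (Euclidean), weights edges
#' by shared-nearest-neighbor Jaccard similarity, and partitions it by
#' Leiden modularity optimization at the given resolution. The resolution
#' controls granularity: smaller values yield fewer, larger communities.
#' Deterministic for a fixed seed.
#'
#' @param scores cells x d matrix of PC scores.
#' @param k_neighbors neighbors per cell (default 20).
#' @param resolution modularity resolution parameter (default 0.02).
#' @param seed integer seed.
#' @param prune discard SNN edges with Jaccard below this (default 1/15).
#' @return integer cluster labels (1-based, sizes decreasing).
#' @export
cluster_graph <- function(scores, k_neighbors = 20, resolution = 0.02,
                          seed = 1, prune = 1 / 15) {
  scores <- as.matrix(scores)
  k <- min(k_neighbors, nrow(scores) - 1L)
  nn <- .knn_indices(scores, k)
  g <- .snn_graph(nn$index, prune = prune)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  lab <- as.integer(igraph::membership(cl))
  ## relabel so cluster 1 is the largest
  sizes <- sort(table(lab), decreasing = TRUE)
  match(lab, as.integer(names(sizes)))
}

#' Density-based isolation filter
#'
#' For each cell, computes the mean Euclidean distance d to its k nearest
#' neighbors; at constant density d^3 scales as 1/n, so n*d^3 is comparable
#' across clusters of different sizes. Cells with n*d^3 above the cutoff sit
#' in regions of low cellular density and carry uncertain cluster
#' assignments.
#'
#' @param scores cells x d matrix of PC scores (one cluster's cells).
#' @param k_neighbors neighbors used for the mean distance (default 20).
#' @param cutoff_nd3 keep cells with n*d^3 <= cutoff; default (\code{NULL})
#'   uses the \code{cutoff_quantile} of n*d^3 within the input.
#' @param cutoff_quantile quantile defining the default cutoff (0.95).
#' @return list(keep = logical mask, nd3 = numeric vector, cutoff = value).
#' @export
isolation_filter <- function(scores, k_neighbors = 20, cutoff_nd3 = NULL,
                             cutoff_quantile = 0.95) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- min(k_neighbors, n - 1L)
  nn <- .knn_indices(scores, k)
  d <- rowMeans(nn$dist)
  nd3 <- n * d^3
  if (is.null(cutoff_nd3))
    cutoff_nd3 <- stats::quantile(nd3, cutoff_quantile, names = FALSE)
  list(keep = nd3 <= cutoff_nd3, nd3 = nd3, cutoff = cutoff_nd3)
}

#' Annotate clusters against a marker table
#'
#' Scores each (cluster, cell type) pair by the mean, over the type's
#' markers, of the cluster-mean LTQ z-scored across clusters. A cluster gets
#' the best-scoring type if it beats the runner-up by at least
#' \code{margin} z-units; otherwise it is "unresolved" — ties are never
#' silently broken.
#'
#' @param labels integer cluster labels, one per cell.
#' @param ltq genes x cells LTQ matrix for the same cells.
#' @param markers data.frame(cell_type, gene); marker ids absent from the
#'   matrix are dropped with a warning.
#' @param margin z-score margin over the runner-up (default 0.5).
#' @return character vector: annotation per cluster (names = cluster ids).
#' @export
annotate_clusters <- function(labels, ltq, markers, margin = 0.5) {
  .assert(all(c("cell_type", "gene") %in% names(markers)),
          "markers needs cell_type and gene columns")
  miss <- setdiff(unique(markers$gene), rownames(ltq))
  if (length(miss)) {
    warning(sprintf("%d marker gene(s) not in matrix: %s", length(miss),
                    paste(utils::head(miss, 5), collapse = ", ")))
    markers <- markers[markers$gene %in% rownames(ltq), , drop = FALSE]
  }
  cl <- sort(unique(labels))
  cm <- vapply(cl, function(c) rowMeans(ltq[, labels == c, drop = FALSE]),
               numeric(nrow(ltq)))  # genes x clusters
  if (length(cl) == 1L) {
    z <- matrix(0, nrow(ltq), 1L, dimnames = list(rownames(ltq), NULL))
  } else {
    mu <- rowMeans(cm); s <- apply(cm, 1, stats::sd)
    z <- (cm - mu) / ifelse(s == 0, 1, s)
    rownames(z) <- rownames(ltq)
  }
  types <- unique(markers$cell_type)
  score <- vapply(types, function(ty) {
    g <- markers$gene[markers$cell_type == ty]
    colMeans(z[g, , drop = FALSE])
  }, numeric(length(cl)))
  score <- matrix(score, nrow = length(cl),
                  dimnames = list(cl, types))
  ann <- apply(score, 1, function(s) {
    o <- order(s, decreasing = TRUE)
    if (length(s) > 1 && s[o[1]] - s[o[2]] < margin) "unresolved"
    else colnames(score)[o[1]]
  })
  stats::setNames(as.character(ann), cl)
}

#' Recursive hierarchical cell typing
#'
#' At every node: re-select high-SNR genes, drop low-RNA cells (per-node,
#' since RNA content is cell-type specific), run centered unscaled PCA,
#' choose the number of PCs by the elbow rule, cluster the cells with
#' Leiden at the depth's scheduled resolution, drop isolated cells
#' (n*d^3 filter), annotate clusters against the marker table, and recurse
#' into each cluster. Recursion stops when clustering returns a single
#' community (the node is a continuum at this granularity) or the node is
#' smaller than \code{min_cells}.
#'
#' @param lm an [ltq_matrix()].
#' @param markers data.frame(cell_type, gene) of known marker genes.
#' @param resolution_schedule numeric vector of Leiden resolutions by tree
#'   depth (default \code{c(0.02, 0.03, 0.07, 0.1)}; the last entry is
#'   recycled for deeper levels).
#' @param counts_totals optional per-cell total UMIs (named) for the
#'   low-RNA filter; \code{NULL} skips that filter.
#' @param snr_threshold SNR gene cutoff per node (default 0.25).
#' @param k_neighbors kNN parameter for clustering and isolation
#'   (default 20).
#' @param n_pcs_max cap on PCs per node (default 10).
#' @param min_cells nodes smaller than this become leaves (default 50).
#' @param max_depth recursion cap (default 5).
#' @param isolation_quantile per-node n*d^3 cutoff quantile (default 0.95);
#'   \code{NULL} disables isolation filtering.
#' @param annotation_margin z-margin for [annotate_clusters()].
#' @param seed integer seed.
#' @return a \code{typing_node} tree; see [typing_leaves()] for flat labels.
#' @export
recursive_typing <- function(lm, markers,
                             resolution_schedule = c(0.02, 0.03, 0.07, 0.1),
                             counts_totals = NULL, snr_threshold = 0.25,
                             k_neighbors = 20, n_pcs_max = 10,
                             min_cells = 50, max_depth = 5,
                             isolation_quantile = 0.95,
                             annotation_margin = 0.5, seed = 1) {
  .assert(inherits(lm, "ltq_matrix"), "lm must be an ltq_matrix")
  .type_node(lm, colnames(lm$ltq), markers, resolution_schedule,
             counts_totals, snr_threshold, k_neighbors, n_pcs_max,
             min_cells, max_depth, isolation_quantile, annotation_margin,
             seed, depth = 0L, annotation = "root")
}

.type_node <- function(lm, cells, markers, sched, totals, snr_thr, k, npc_max,
                       min_cells, max_depth, iso_q, margin, seed, depth,
                       annotation) {
  node <- list(cells = cells, depth = depth, annotation = annotation,
               excluded = data.frame(cell_id = character(),
                                     filter = character()),
               children = list())
  class(node) <- "typing_node"
  if (length(cells) < max(min_cells, k + 2L) || depth >= max_depth)
    return(node)

  ## per-node low-RNA filter
  if (!is.null(totals)) {
    keep <- low_rna_filter(totals[cells])
    node$excluded <- rbind(node$excluded,
                           data.frame(cell_id = cells[!keep],
                                      filter = rep("low_rna", sum(!keep))))
    cells <- cells[keep]
  }
  ## per-node SNR gene selection
  sub <- ltq_matrix(lm$ltq[, cells, drop = FALSE], lm$gene_error)
  genes <- snr_genes(sub, snr_thr)
  if (length(genes) < 2L) return(node)
  pca <- run_pca(sub$ltq[genes, , drop = FALSE], n_pcs_max = npc_max)
  npc <- choose_n_pcs(pca$variance_explained)
  sc <- pca$scores[, seq_len(npc), drop = FALSE]

  ## per-node isolation filter
  if (!is.null(iso_q)) {
    iso <- isolation_filter(sc, k_neighbors = k, cutoff_quantile = iso_q)
    node$excluded <- rbind(node$excluded,
                           data.frame(cell_id = cells[!iso$keep],
                                      filter = rep("isolation",
                                                   sum(!iso$keep))))
    cells <- cells[iso$keep]
    sc <- sc[iso$keep, , drop = FALSE]
  }
  if (length(cells) < max(min_cells, k + 2L)) return(node)

  res <- sched[min(depth + 1L, length(sched))]
  labels <- cluster_graph(sc, k_neighbors = k, resolution = res,
                          seed = derive_seed(seed, paste0("node", depth)))
  node$genes <- genes
  node$pca <- pca
  node$n_pcs <- npc
  node$resolution <- res
  node$cluster_labels <- stats::setNames(labels, cells)
  if (length(unique(labels)) == 1L) {
    node$continuum <- TRUE  # one community: continuum at this resolution
    return(node)
  }
  ann <- annotate_clusters(labels, lm$ltq[, cells, drop = FALSE], markers,
                           margin = margin)
  node$cluster_annotation <- ann
  for (c in sort(unique(labels))) {
    child_cells <- cells[labels == c]
    node$children[[length(node$children) + 1L]] <-
      .type_node(lm, child_cells, markers, sched, totals, snr_thr, k,
                 npc_max, min_cells, max_depth, iso_q, margin,
                 derive_seed(seed, paste0("d", depth, "c", c)),
                 depth + 1L, ann[[as.character(c)]])
  }
  node
}

#' @export
print.typing_node <- function(x, indent = "", ...) {
  cat(sprintf("%s%s: %d cells (depth %d%s)\n", indent, x$annotation,
              length(x$cells), x$depth,
              if (isTRUE(x$continuum)) ", continuum" else ""))
  for (ch in x$children) print(ch, indent = paste0(indent, "  "))
  invisible(x)
}

#' Flatten a typing tree to per-cell leaf labels
#'
#' Every retained cell appears in exactly one leaf; cells excluded by the
#' per-node filters are absent (they are logged in each node's
#' \code{excluded} table).
#'
#' @param node a \code{typing_node} from [recursive_typing()].
#' @return named character vector: leaf annotation per cell id.
#' @export
typing_leaves <- function(node) {
  if (!length(node$children)) {
    cells <- if (!is.null(node$cluster_labels))
      names(node$cluster_labels) else node$cells
    ## cells excluded at this node (filters) are dropped from the leaf
    if (nrow(node$excluded))
      cells <- setdiff(cells, node$excluded$cell_id)
    return(stats::setNames(rep(node$annotation, length(cells)), cells))
  }
  do.call(c, lapply(node$children, typing_leaves))
}
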