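#' UMI count matrix container
#'
#' Wraps a genes x cells matrix of non-negative integer UMI counts together
#' with per-cell metadata (sample and timepoint). Gene and cell identifiers
#' are carried as the matrix dimnames and must be unique.
#'
#' @param counts genes x cells matrix (dense or \code{Matrix} sparse) of
#'   non-negative integers with rownames (gene ids) and colnames (cell ids).
#' @param cell_meta data.frame with one row per cell; must contain a
#'   \code{cell_id} column matching \code{colnames(counts)}. Typically also
#'   \code{sample} and \code{timepoint}.
#' @return an object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "counts must carry gene ids (rownames) and cell ids (colnames)")
  .assert(!anyDuplicated(rownames(counts)), "gene ids must be unique")
  .assert(!anyDuplicated(colnames(counts)), "cell ids must be unique")
  v <- if (inherits(counts, "Matrix")) counts@x else counts
  .assert(all(v >= 0), "counts must be non-negative")
  .assert(all(v == round(v)), "counts must be integers")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(counts),
                            sample = "sample1", timepoint = 1L,
                            stringsAsFactors = FALSE)
  }
  .assert(is.data.frame(cell_meta) && "cell_id" %in% names(cell_meta),
          "cell_meta must be a data.frame with a cell_id column")
  .assert(all(colnames(counts) %in% cell_meta$cell_id),
          "every cell must have metadata")
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell_id), ,
                         drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  tp <- table(x$cell_meta$timepoint)
  cat("cells per timepoint:",
      paste(sprintf("t%s=%d", names(tp), as.integer(tp)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Log transcription quotient (LTQ) matrix container
#'
#' Denoised natural-log estimates of each gene's fraction of a cell's
#' transcriptome, plus a per-gene mean sampling error (the average posterior
#' standard deviation across cells).
#'
#' @param ltq genes x cells numeric matrix (natural-log scale) with dimnames.
#' @param gene_error numeric vector, one non-negative value per gene.
#' @return an object of class \code{ltq_matrix}.
#' @export
ltq_matrix <- function(ltq, gene_error) {
  .assert(!is.null(rownames(ltq)) && !is.null(colnames(ltq)),
          "ltq must carry gene and cell ids as dimnames")
  .assert(all(is.finite(ltq)), "ltq values must be finite")
  .assert(length(gene_error) == nrow(ltq), "one gene_error per gene")
  .assert(all(is.finite(gene_error)) && all(gene_error >= 0),
          "gene_error must be finite and >= 0")
  names(gene_error) <- rownames(ltq)
  structure(list(ltq = ltq, gene_error = gene_error),
            class = "ltq_matrix")
}

#' @export
print.ltq_matrix <- function(x, ...) {
  cat(sprintf("ltq_matrix: %d genes x %d cells (natural-log scale)\n",
              nrow(x$ltq), ncol(x$ltq)))
  cat(sprintf("mean gene sampling error: %.3f\n", mean(x$gene_error)))
  invisible(x)
}

#' @export
dim.ltq_matrix <- function(x) dim(x$ltq)
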