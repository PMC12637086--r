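## Reading and writing the standard exchange formats: MTX triplet
## (matrix.mtx, features.tsv, barcodes.tsv) plus metadata CSV, dense count
## CSV, LTQ tables and marker tables.

#' Write a count matrix as an MTX triplet directory
#'
#' Writes \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv} and
#' \code{metadata.csv} (cell_id, sample, timepoint, ...) into \code{dir}.
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_mtx <- function(cm, dir) {
  .assert(inherits(cm, "count_matrix"), "cm must be a count_matrix")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(cm$counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cm$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  utils::write.csv(cm$cell_meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix from an MTX triplet directory (or a dense CSV)
#'
#' @param path directory containing \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv} and optionally \code{metadata.csv}; or a dense CSV
#'   file (genes x cells, first column = gene id).
#' @return a [count_matrix()].
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    .assert(file.exists(mtx), "missing %s", mtx)
    m <- as.matrix(Matrix::readMM(mtx))
    rownames(m) <- readLines(file.path(path, "features.tsv"))
    colnames(m) <- readLines(file.path(path, "barcodes.tsv"))
    meta_path <- file.path(path, "metadata.csv")
    meta <- if (file.exists(meta_path))
      utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
    return(count_matrix(m, meta))
  }
  .assert(file.exists(path), "no such file or directory: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m)
}

#' Write an LTQ matrix (values + per-gene errors) as CSV
#'
#' @param lm an [ltq_matrix()].
#' @param ltq_path CSV for the genes x cells LTQ values.
#' @param error_path CSV for the per-gene errors.
#' @export
write_ltq <- function(lm, ltq_path, error_path) {
  .assert(inherits(lm, "ltq_matrix"), "lm must be an ltq_matrix")
  utils::write.csv(data.frame(gene = rownames(lm$ltq), lm$ltq,
                              check.names = FALSE),
                   ltq_path, row.names = FALSE)
  utils::write.csv(data.frame(gene = names(lm$gene_error),
                              gene_error = lm$gene_error),
                   error_path, row.names = FALSE)
  invisible(ltq_path)
}

#' Read an LTQ matrix written by [write_ltq()]
#'
#' @param ltq_path,error_path the two CSVs.
#' @return an [ltq_matrix()].
#' @export
read_ltq <- function(ltq_path, error_path) {
  df <- utils::read.csv(ltq_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  err <- utils::read.csv(error_path, stringsAsFactors = FALSE)
  ltq_matrix(m, err$gene_error[match(rownames(m), err$gene)])
}
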