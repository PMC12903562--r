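#' Write a count matrix as MTX with TSV sidecars
#'
#' Writes `matrix.mtx` (MatrixMarket, genes x cells), `barcodes.tsv` (cell
#' ids) and `features.tsv` (gene ids) into `dir`.
#'
#' @param x SingleCellExperiment or genes x cells matrix.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(x, dir) {
  counts <- .get_counts(x)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read an MTX + TSV directory into a SingleCellExperiment
#'
#' @param dir directory holding `matrix.mtx`, `barcodes.tsv`, `features.tsv`.
#' @return SingleCellExperiment with a `counts` assay.
#' @export
read_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}
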