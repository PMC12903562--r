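#' Cell-level QC thresholds
#'
#' All bounds are strict inequalities ("less than" / "more than"), matching
#' the common reporting convention: a cell at exactly the mitochondrial cutoff
#' is removed, a cell with exactly `min_genes` detected genes is removed.
#'
#' @param max_mito_fraction cells must have mito fraction strictly below this.
#' @param min_genes cells must have strictly more detected genes than this.
#' @param max_genes optional strict upper bound on detected genes.
#' @param min_cells_per_gene gene filter companion threshold (see
#'   [filter_genes()]).
#' @return a `kdn_qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.15, min_genes = 1200,
                          max_genes = NULL, min_cells_per_gene = 3) {
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must be in [0, 1]")
  if (min_genes < 0) stop("min_genes must be >= 0")
  if (!is.null(max_genes) && max_genes <= min_genes)
    stop("max_genes must exceed min_genes")
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_genes = min_genes, max_genes = max_genes,
                 min_cells_per_gene = min_cells_per_gene),
            class = "kdn_qc_thresholds")
}

#' Named QC presets
#'
#' Three shipped presets: `"time-series"` (mito < 0.15, genes > 1200, gene in
#' >= 3 cells), `"coculture"` (300 < features < 8000, mito < 0.30), and
#' `"cohort"` (mito < 0.10, genes < 8000).
#'
#' @param name preset name.
#' @return a [qc_thresholds()] object.
#' @export
qc_preset <- function(name = c("time-series", "coculture", "cohort")) {
  name <- match.arg(name)
  switch(name,
    "time-series" = qc_thresholds(0.15, 1200, NULL, 3),
    "coculture"   = qc_thresholds(0.30, 300, 8000, 3),
    "cohort"      = qc_thresholds(0.10, 0, 8000, 3))
}

.mito_fraction <- function(counts, mito_prefixes) {
  pat <- paste0("^(", paste(mito_prefixes, collapse = "|"), ")")
  mito <- grepl(pat, rownames(counts))
  tot <- Matrix::colSums(counts)
  if (!any(mito)) return(list(found = FALSE, frac = rep(0, ncol(counts)), tot = tot))
  list(found = TRUE, frac = Matrix::colSums(counts[mito, , drop = FALSE]) /
         pmax(tot, 1), tot = tot)
}

#' Filter cells on mitochondrial fraction and detected-gene count
#'
#' Keeps cells with mitochondrial fraction strictly below
#' `thr$max_mito_fraction` and strictly more than `thr$min_genes` detected
#' genes (and strictly fewer than `thr$max_genes` when set). Cell order is
#' preserved. Mitochondrial genes are recognized by name prefix; if none are
#' found while a mito bound is active, the mito filter is skipped with a
#' warning.
#'
#' @param cells SingleCellExperiment or genes x cells count matrix.
#' @param thr a [qc_thresholds()].
#' @param mito_prefixes gene-name prefixes marking mitochondrial genes.
#' @return the filtered object, same class as the input.
#' @export
filter_cells <- function(cells, thr = qc_thresholds(),
                         mito_prefixes = c("MT-", "mt-")) {
  counts <- .get_counts(cells)
  .stopifnot_named(counts, "cells")
  mi <- .mito_fraction(counts, mito_prefixes)
  keep <- rep(TRUE, ncol(counts))
  if (thr$max_mito_fraction < 1) {
    if (!mi$found) {
      warning("no mitochondrial genes matched prefixes ",
              paste(mito_prefixes, collapse = ", "),
              "; mitochondrial filter skipped")
    } else {
      keep <- keep & (mi$frac < thr$max_mito_fraction)
    }
  }
  n_genes <- Matrix::colSums(counts > 0)
  keep <- keep & (n_genes > thr$min_genes)
  if (!is.null(thr$max_genes)) keep <- keep & (n_genes < thr$max_genes)
  cells[, keep, drop = FALSE]
}

#' Drop genes detected in too few cells
#'
#' Retains genes with nonzero counts in at least `min_cells` cells ("detected
#' in less than `min_cells` cells" excluded — a gene seen in exactly
#' `min_cells` cells is kept).
#'
#' @param cells SingleCellExperiment or genes x cells count matrix.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @return the filtered object, same class as the input.
#' @export
filter_genes <- function(cells, min_cells = 3) {
  counts <- .get_counts(cells)
  keep <- Matrix::rowSums(counts > 0) >= min_cells
  cells[keep, , drop = FALSE]
}

#' Drop underperforming probes relative to each gene's best probe
#'
#' Per gene, computes every probe's mean raw count across all cells and keeps
#' probes whose mean is at least `rel_threshold` times the best probe's mean
#' for that gene. The best probe always passes its own threshold, so no gene
#' is ever emptied. Genes with zero total counts keep all probes (threshold
#' 0), with a message.
#'
#' @param probes SingleCellExperiment of probes x cells with a `gene` column
#'   in `rowData`, or a matrix plus `gene_map`.
#' @param rel_threshold fraction of the best probe's mean (default 0.2, the
#'   20% rule).
#' @param gene_map character vector mapping probe rows to genes (required for
#'   matrix input).
#' @return list with `probes` (filtered, same class as input) and `report`
#'   (data.frame: probe_id, gene, mean_count, threshold, keep).
#' @export
filter_probes <- function(probes, rel_threshold = 0.2, gene_map = NULL) {
  counts <- .get_counts(probes)
  .stopifnot_named(counts, "probes")
  if (is.null(gene_map)) {
    if (!is(probes, "SummarizedExperiment") ||
        is.null(SummarizedExperiment::rowData(probes)$gene))
      stop("gene_map required (or rowData(probes)$gene)")
    gene_map <- SummarizedExperiment::rowData(probes)$gene
  }
  if (length(gene_map) != nrow(counts))
    stop("gene_map must name one gene per probe row")
  if (rel_threshold < 0 || rel_threshold > 1)
    stop("rel_threshold must be in [0, 1]")
  pm <- Matrix::rowMeans(counts)
  best <- tapply(pm, gene_map, max)[gene_map]
  zero_genes <- unique(gene_map[best == 0])
  if (length(zero_genes))
    message(length(zero_genes),
            " gene(s) with zero total counts: all their probes kept")
  thr <- rel_threshold * best
  keep <- pm >= thr
  report <- data.frame(probe_id = rownames(counts), gene = gene_map,
                       mean_count = as.numeric(pm),
                       threshold = as.numeric(thr), keep = as.logical(keep),
                       stringsAsFactors = FALSE)
  list(probes = probes[keep, , drop = FALSE], report = report)
}

#' Aggregate probe counts to gene level by the per-gene mean
#'
#' For every cell and gene, the gene value is the arithmetic mean of that
#' gene's remaining probes. Values are fractional (not re-rounded);
#' downstream normalization accepts non-integer counts. Genes with no
#' remaining probes are dropped.
#'
#' @param probes SingleCellExperiment of probes x cells (with
#'   `rowData()$gene`) or matrix plus `gene_map`.
#' @param gene_map probe-to-gene map for matrix input.
#' @return SingleCellExperiment (or matrix, matching input) of genes x cells.
#' @export
aggregate_probes <- function(probes, gene_map = NULL) {
  counts <- .get_counts(probes)
  was_se <- is(probes, "SummarizedExperiment")
  if (is.null(gene_map)) {
    if (!was_se || is.null(SummarizedExperiment::rowData(probes)$gene))
      stop("gene_map required (or rowData(probes)$gene)")
    gene_map <- SummarizedExperiment::rowData(probes)$gene
  }
  genes <- unique(gene_map)
  # sparse gene x probe indicator scaled by 1/probes-per-gene gives the mean
  nper <- table(gene_map)[genes]
  ind <- Matrix::sparseMatrix(i = match(gene_map, genes),
                              j = seq_along(gene_map),
                              x = 1 / as.numeric(nper[match(gene_map, genes)]),
                              dims = c(length(genes), length(gene_map)))
  agg <- ind %*% counts
  rownames(agg) <- genes
  colnames(agg) <- colnames(counts)
  if (was_se) {
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = agg),
      colData = SummarizedExperiment::colData(probes))
  } else {
    as.matrix(agg)
  }
}
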