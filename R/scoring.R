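#' Library-size normalization with natural-log transform
#'
#' Scales each cell to `scale_factor` total counts and applies `log1p`:
#' `value = ln(1 + count * scale_factor / cell_total)`. This is the standard
#' log-normalization of single-cell toolkits at its default scale factor.
#'
#' @param cells SingleCellExperiment or genes x cells (possibly fractional)
#'   count matrix.
#' @param scale_factor per-cell count target (default 10,000).
#' @return for matrix input, the normalized genes x cells matrix; for a
#'   SingleCellExperiment, the object with a `logcounts` assay added.
#' @export
lognormalize <- function(cells, scale_factor = 10000) {
  counts <- .get_counts(cells)
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    stop("cell(s) with zero total counts: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  }
  norm <- log1p(counts %*% Matrix::Diagonal(x = scale_factor / tot))
  dimnames(norm) <- dimnames(counts)
  if (is(cells, "SummarizedExperiment")) {
    SummarizedExperiment::assay(cells, "logcounts") <- norm
    cells
  } else {
    as.matrix(norm)
  }
}

.get_logcounts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x, "logcounts"))
  x
}

#' Expression-bin-matched gene-module score
#'
#' Per-cell score of a gene set against an expression-matched control: genes
#' are binned into `n_bins` by their across-cell mean expression; for each set
#' gene, `n_ctrl` control genes are sampled (seeded, without replacement
#' within each bin, set genes excluded) from that gene's bin; the score is the
#' mean expression of the set genes minus the mean expression of the pooled
#' control genes. Scores are invariant under a global additive shift of the
#' matrix and center near zero for random gene sets.
#'
#' @param norm normalized genes x cells matrix (or SingleCellExperiment with
#'   a `logcounts` assay).
#' @param gene_set character vector of gene ids; ids absent from the matrix
#'   are dropped with a warning.
#' @param n_bins number of mean-expression bins.
#' @param n_ctrl control genes drawn per set gene.
#' @param seed integer seed for the control draw.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  m <- .get_logcounts(norm)
  .stopifnot_named(m, "norm")
  present <- intersect(gene_set, rownames(m))
  if (!length(present))
    stop("none of the gene_set genes are present in the matrix")
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present),
            " gene(s) of the set absent from the matrix; dropped")
  set.seed(as.integer(seed))
  gene_means <- Matrix::rowMeans(m)
  # rank-based binning (equal-occupancy), robust to skewed mean distributions
  bins <- cut(rank(gene_means, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- rownames(m)
  ctrl <- character(0)
  for (gene in present) {
    pool <- setdiff(names(bins)[bins == bins[gene]], gene_set)
    if (!length(pool)) next
    ctrl <- c(ctrl, sample(pool, min(n_ctrl, length(pool))))
  }
  ctrl <- unique(ctrl)
  set_mean <- Matrix::colMeans(m[present, , drop = FALSE])
  ctrl_mean <- if (length(ctrl))
    Matrix::colMeans(m[ctrl, , drop = FALSE]) else 0
  as.numeric(set_mean - ctrl_mean) |> setNames(colnames(m))
}

#' Score several signatures and assign each cell to at most one
#'
#' Computes [module_score()] for each signature, then labels every cell with
#' the signature of its highest score, provided that score strictly exceeds
#' the across-cell mean of that signature's scores; otherwise the cell is
#' `"non-assigned"`. With `mean_rule = "global"` the comparison mean is the
#' pooled mean over all signatures' scores instead (the per-signature rule is
#' the default reading).
#'
#' @param norm normalized matrix or SingleCellExperiment with `logcounts`.
#' @param signatures named list of gene-id vectors (>= 2 signatures).
#' @param mean_rule `"per-signature"` (default) or `"global"`.
#' @param ... passed to [module_score()] (`n_bins`, `n_ctrl`, `seed`).
#' @return list with `scores` (cells x signatures matrix), `signature_means`,
#'   and `assignment` (factor per cell; levels = signatures +
#'   `"non-assigned"`). Argmax ties are broken by signature input order (a
#'   message is emitted when ties occur).
#' @export
assign_signature <- function(norm, signatures,
                             mean_rule = c("per-signature", "global"), ...) {
  mean_rule <- match.arg(mean_rule)
  if (length(signatures) < 2 || is.null(names(signatures)))
    stop("signatures must be a named list of >= 2 gene sets")
  scores <- sapply(signatures, function(gs) module_score(norm, gs, ...))
  sig_means <- colMeans(scores)
  cmp_mean <- if (mean_rule == "global") rep(mean(scores), ncol(scores)) else sig_means
  best_j <- max.col(scores, ties.method = "first")
  n_ties <- sum(apply(scores, 1, function(r) sum(r == max(r)) > 1))
  if (n_ties > 0)
    message(n_ties, " cell(s) with tied top scores; ties broken by signature order")
  best_score <- scores[cbind(seq_len(nrow(scores)), best_j)]
  lab <- ifelse(best_score > cmp_mean[best_j], names(signatures)[best_j],
                "non-assigned")
  list(scores = scores,
       signature_means = sig_means,
       assignment = factor(lab, levels = c(names(signatures), "non-assigned")) |>
         setNames(rownames(scores)))
}

#' Rank-sum differential expression with effect/significance thresholds
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two cell groups on
#' normalized values, with a fold change computed on de-logged means:
#' `log2FC = log2((mean(expm1(A)) + 1) / (mean(expm1(B)) + 1))`. A gene passes
#' when `|log2FC| >= lfc_threshold` and raw `p < alpha` (the pass rule uses
#' the raw p-value; Benjamini-Hochberg adjusted p-values are reported
#' alongside).
#'
#' @param norm normalized genes x cells matrix or SingleCellExperiment with
#'   `logcounts`.
#' @param groupA,groupB disjoint cell id (or column index) vectors.
#' @param lfc_threshold minimum absolute log2 fold change (default 0.2).
#' @param alpha raw p-value cutoff (default 0.05).
#' @return data.frame(gene, log2fc, p_value, p_adj, pass) sorted by p-value.
#' @export
rank_sum_de <- function(norm, groupA, groupB, lfc_threshold = 0.2,
                        alpha = 0.05) {
  m <- .get_logcounts(norm)
  idx <- function(g) if (is.character(g)) match(g, colnames(m)) else g
  a <- idx(groupA); b <- idx(groupB)
  if (anyNA(a) || anyNA(b)) stop("unknown cell ids in group definition")
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(intersect(a, b))) stop("groups overlap")
  ma <- as.matrix(m[, a, drop = FALSE]); mb <- as.matrix(m[, b, drop = FALSE])
  # wilcox.test picks the exact distribution for small tie-free groups and
  # the tie-corrected normal approximation otherwise
  p <- vapply(seq_len(nrow(m)), function(i) {
    suppressWarnings(wilcox.test(ma[i, ], mb[i, ])$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # constant genes carry no evidence
  mA <- rowMeans(expm1(ma)); mB <- rowMeans(expm1(mb))
  lfc <- log2((mA + 1) / (mB + 1))
  res <- data.frame(gene = rownames(m), log2fc = lfc, p_value = p,
                    p_adj = p.adjust(p, "BH"),
                    pass = abs(lfc) >= lfc_threshold & p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$p_value), ]
}

#' Read gene sets from a GMT or two-column CSV file
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' CSV: columns `set` (or first column) and `gene` (or second column).
#'
#' @param path file path; format chosen by extension (`.gmt` vs anything else).
#' @return named list of gene-id character vectors.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[[`, character(1), 1)
    return(sets)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  split(df[[2]], df[[1]])
}
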