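#' Rank genes by their contribution to the trained classifier
#'
#' Three importance metrics are provided because the ranking metric behind
#' "top predictive genes" is a modeling choice. The default
#' `"weight_delta_l2"` scores each input gene by the L2 norm of the change of
#' its first-layer weight row over training — the accumulated gradient a gene
#' attracted, which removes the initialization noise floor that a raw weight
#' norm carries. `"input_weight_l2"` is that raw norm of the final weights;
#' `"permutation"` scores a gene by the drop in accuracy when its column is
#' permuted (seeded), the principled but costliest alternative. The top
#' `round(fraction * n_genes)` genes form the classifier gene set.
#'
#' @param model a trained `kdn_mlp`.
#' @param fraction selected fraction of ranked genes (default 0.05).
#' @param method `"weight_delta_l2"`, `"input_weight_l2"` or `"permutation"`.
#' @param X,labels validation data (genes x cells + per-cell labels),
#'   required for the permutation method.
#' @param seed seed for the permutation draws.
#' @return a `kdn_classifier_genes` list: `ranking` (data.frame gene,
#'   importance, sorted), `fraction`, `selected` (character vector of
#'   `round(fraction * n)` top gene ids).
#' @export
extract_classifier_genes <- function(model, fraction = 0.05,
                                     method = c("weight_delta_l2",
                                                "input_weight_l2",
                                                "permutation"),
                                     X = NULL, labels = NULL, seed = 1L) {
  if (!is(model, "kdn_mlp")) stop("model must be a trained kdn_mlp")
  method <- match.arg(method)
  genes <- model$features
  if (method == "weight_delta_l2") {
    imp <- sqrt(rowSums((model$weights[[1]] - model$w1_init)^2))
  } else if (method == "input_weight_l2") {
    imp <- sqrt(rowSums(model$weights[[1]]^2))
  } else {
    if (is.null(X) || is.null(labels))
      stop("permutation importance needs validation data (X, labels)")
    m <- .get_logcounts(X)
    base <- predict(model, m, truth = labels)$accuracy
    set.seed(as.integer(seed))
    xs <- as.matrix(m[genes, , drop = FALSE])
    imp <- vapply(seq_along(genes), function(i) {
      xp <- xs
      xp[i, ] <- xp[i, sample(ncol(xp))]
      base - predict(model, xp, truth = labels)$accuracy
    }, numeric(1))
  }
  ord <- order(imp, decreasing = TRUE)
  ranking <- data.frame(gene = genes[ord], importance = imp[ord],
                        rank = seq_along(genes), stringsAsFactors = FALSE)
  n_sel <- round(fraction * length(genes))
  structure(list(ranking = ranking, fraction = fraction, method = method,
                 selected = ranking$gene[seq_len(n_sel)]),
            class = "kdn_classifier_genes")
}

#' @export
print.kdn_classifier_genes <- function(x, ...) {
  cat("classifier gene set:", length(x$selected), "of",
      nrow(x$ranking), "genes (fraction", x$fraction,
      ", method", x$method, ")\n")
  invisible(x)
}

#' Project a labeled cohort into classifier-defined dosage groups
#'
#' Restricts the cohort's ductal cells to the classifier genes, normalizes,
#' averages per sample, clusters the per-sample mean profiles
#' (hierarchical, complete linkage, cut at `k`), names the groups by
#' ascending mean expression of `marker_gene` in their ductal cells, and
#' reports the cell-type composition of each group over all cells of the
#' grouped samples.
#'
#' @param cohort SingleCellExperiment with `colData(sample_id, celltype)`
#'   (must contain ductal cells) and a `counts` assay.
#' @param classifiers a `kdn_classifier_genes` object or character vector of
#'   gene ids.
#' @param marker_gene gene used to order the groups (default `"KRAS"`).
#' @param k number of sample groups (default 3).
#' @param linkage hclust method.
#' @return a `kdn_cohort_grouping` list: `sample_groups` (named factor),
#'   `group_marker_means` (ascending), `proportions` (group x celltype, rows
#'   sum to 1), `counts` (group x celltype cell counts), `n_classifier_used`.
#' @export
cohort_group <- function(cohort, classifiers, marker_gene = "KRAS", k = 3,
                         linkage = "complete") {
  if (!is(cohort, "SummarizedExperiment"))
    stop("cohort must be a SingleCellExperiment with cell metadata")
  cd <- SummarizedExperiment::colData(cohort)
  if (is.null(cd$celltype) || is.null(cd$sample_id))
    stop("cohort colData must provide celltype and sample_id")
  if (!"ductal" %in% cd$celltype) stop("cohort contains no ductal cells")
  genes <- if (is(classifiers, "kdn_classifier_genes")) classifiers$selected
           else as.character(classifiers)
  present <- intersect(genes, rownames(cohort))
  if (!length(present)) stop("no classifier gene present in the cohort")

  ductal <- cohort[, cd$celltype == "ductal"]
  norm <- lognormalize(.get_counts(ductal))
  samples <- unique(cd$sample_id)
  if (length(samples) < k)
    stop("only ", length(samples), " samples; cannot form k = ", k, " groups")
  ductal_sample <- cd$sample_id[cd$celltype == "ductal"]
  prof <- sapply(samples, function(s)
    Matrix::rowMeans(norm[present, ductal_sample == s, drop = FALSE]))
  cl <- cutree(hclust(dist(t(prof)), method = linkage), k = k)

  if (!marker_gene %in% rownames(norm))
    stop("marker gene ", marker_gene, " not in cohort")
  marker_by_sample <- vapply(samples, function(s)
    mean(norm[marker_gene, ductal_sample == s]), numeric(1))
  named <- name_groups(cl, marker_by_sample)
  sample_groups <- named$labels
  names(sample_groups) <- samples

  cell_group <- sample_groups[match(cd$sample_id, samples)]
  counts <- table(group = cell_group, celltype = cd$celltype)
  prop <- sweep(counts, 1, rowSums(counts), `/`)
  structure(list(sample_groups = sample_groups,
                 group_marker_means = named$group_means,
                 proportions = prop, counts = counts,
                 n_classifier_used = length(present)),
            class = "kdn_cohort_grouping")
}

#' Compare cell-type composition across cohort groups
#'
#' Overall chi-square test on the group x celltype cell-count table, plus
#' per-celltype post-hoc tests (each celltype versus all others, 2 x k
#' tables) with Benjamini-Hochberg correction. Warns when more than 20% of
#' the table's expected counts fall below 1.
#'
#' @param grouping a `kdn_cohort_grouping` (or a group x celltype count
#'   matrix/table).
#' @return list(overall = data.frame(statistic, df, p_value),
#'   per_celltype = data.frame(celltype, statistic, p_value, p_adj)).
#' @export
composition_compare <- function(grouping) {
  tab <- if (is(grouping, "kdn_cohort_grouping")) grouping$counts
         else as.table(as.matrix(grouping))
  if (nrow(tab) < 2) stop("need >= 2 groups to compare composition")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (mean(expected < 1) > 0.2)
    warning("more than 20% of expected counts are below 1; ",
            "chi-square approximation is unreliable")
  ov <- suppressWarnings(chisq.test(tab))
  per <- lapply(colnames(tab), function(ct) {
    sub <- rbind(tab[, ct], rowSums(tab) - tab[, ct])
    ts <- suppressWarnings(chisq.test(sub))
    data.frame(celltype = ct, statistic = unname(ts$statistic),
               p_value = ts$p.value, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  per$p_adj <- p.adjust(per$p_value, "BH")
  list(overall = data.frame(statistic = unname(ov$statistic),
                            df = unname(ov$parameter),
                            p_value = ov$p.value),
       per_celltype = per)
}
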