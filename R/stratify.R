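#' Dosage grouping of cells from a single gene's expression
#'
#' Stratifies cells into `k` dosage groups by agglomerative hierarchical
#' clustering of the (1-D, typically normalized) expression values of one
#' gene under Euclidean distance, cutting the tree at `k` and renaming the
#' groups by ascending group mean (`low` / `intermediate` / `high` for
#' k = 3). For complete linkage the implementation compresses ties to unique
#' values before clustering — duplicated points merge at height zero and then
#' behave exactly like a single point under the maximum linkage, so the
#' partition is identical to the naive full-distance-matrix computation (this
#' equivalence is exercised in the test suite); other linkages use the full
#' matrix.
#'
#' @param values named numeric vector: one expression value per cell.
#' @param k number of groups (default 3).
#' @param linkage hclust agglomeration method (default `"complete"`).
#' @param use_kmeans if TRUE, Lloyd's k-means (on the 1-D values, seeded by
#'   quantile centers) replaces the tree cut — a sensitivity-analysis switch,
#'   not the default pathway.
#' @return a `kdn_dosage_labels` list: `labels` (named factor), `group_means`
#'   (ascending), `marker` (attribute only if known), `method`.
#' @export
dosage_cluster <- function(values, k = 3, linkage = "complete",
                           use_kmeans = FALSE) {
  if (is.null(names(values))) names(values) <- seq_along(values)
  uv <- unique(values)
  if (length(uv) < k)
    stop("only ", length(uv), " distinct expression values; reduce k (= ",
         k, ") or provide richer input")
  if (use_kmeans) {
    centers <- quantile(values, probs = seq(0.5, k - 0.5) / k, names = FALSE)
    km <- stats::kmeans(values, centers = matrix(unique(centers)), iter.max = 50)
    raw <- km$cluster
  } else if (identical(linkage, "complete")) {
    hc <- hclust(dist(uv), method = "complete")
    cl_u <- cutree(hc, k = k)
    raw <- cl_u[match(values, uv)]
  } else {
    hc <- hclust(dist(values), method = linkage)
    raw <- cutree(hc, k = k)
  }
  names(raw) <- names(values)
  out <- name_groups(raw, values)
  out$method <- list(linkage = if (use_kmeans) "kmeans" else linkage, k = k)
  out
}

#' Rename cluster labels by ascending marker expression
#'
#' Orders groups by their mean marker value and renames them `low`,
#' `intermediate`, `high` (k = 3) or `group1..k` otherwise. Ties between
#' group means are broken by group size, larger first, with a message.
#' Idempotent after the first application.
#'
#' @param labels per-cell group labels (any coding).
#' @param marker_values per-cell numeric marker expression, same order.
#' @return a `kdn_dosage_labels` list (`labels`, `group_means`).
#' @export
name_groups <- function(labels, marker_values) {
  stopifnot(length(labels) == length(marker_values))
  cell_ids <- names(labels)
  labels <- as.character(labels)
  names(labels) <- cell_ids
  grp <- unique(labels)
  means <- vapply(grp, function(g) mean(marker_values[labels == g]), numeric(1))
  sizes <- vapply(grp, function(g) sum(labels == g), numeric(1))
  if (anyDuplicated(means))
    message("tied group means; ties broken by group size (larger first)")
  ord <- order(means, -sizes)
  k <- length(grp)
  new_names <- if (k == 3) .DOSAGE_LEVELS else paste0("group", seq_len(k))
  mapping <- setNames(new_names, grp[ord])
  lab <- factor(mapping[labels], levels = new_names)
  names(lab) <- names(labels)
  structure(list(labels = lab,
                 group_means = setNames(means[ord], new_names)),
            class = "kdn_dosage_labels")
}

#' @export
print.kdn_dosage_labels <- function(x, ...) {
  cat("Dosage labels for", length(x$labels), "cells\n")
  print(table(x$labels))
  cat("group means:",
      paste(names(x$group_means), signif(x$group_means, 4),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Transfer reference labels to query cells by PCA projection and kNN vote
#'
#' A deliberately simple label-transfer scheme (not anchor-based): principal
#' components are fit on the reference cells only (over the genes shared with
#' the query), query cells are projected into that space, and each query cell
#' takes the majority label of its `k_neighbors` nearest reference cells,
#' with confidence equal to the winning vote fraction.
#'
#' @param reference normalized genes x cells matrix (or SingleCellExperiment
#'   with `logcounts`) for the labeled reference.
#' @param ref_labels per-reference-cell labels.
#' @param query normalized genes x cells matrix (or SCE) to annotate.
#' @param n_pcs number of principal components (default 30).
#' @param k_neighbors neighbors in the vote (default 15).
#' @return data.frame(cell_id, label, confidence).
#' @export
transfer_labels <- function(reference, ref_labels, query, n_pcs = 30,
                            k_neighbors = 15) {
  ref <- .get_logcounts(reference); qry <- .get_logcounts(query)
  shared <- intersect(rownames(ref), rownames(qry))
  if (!length(shared)) stop("no shared genes between reference and query")
  if (length(shared) < 50)
    warning("only ", length(shared), " shared genes; transfer may be unstable")
  stopifnot(length(ref_labels) == ncol(ref))
  r <- t(as.matrix(ref[shared, , drop = FALSE]))
  q <- t(as.matrix(qry[shared, , drop = FALSE]))
  n_pcs <- min(n_pcs, ncol(r) - 1, nrow(r) - 1)
  pc <- prcomp(r, center = TRUE, scale. = FALSE, rank. = n_pcs)
  r_pc <- pc$x
  q_pc <- sweep(q, 2, pc$center) %*% pc$rotation
  k_neighbors <- min(k_neighbors, nrow(r_pc))
  pred <- class::knn(train = r_pc, test = q_pc,
                     cl = factor(ref_labels), k = k_neighbors, prob = TRUE)
  data.frame(cell_id = if (!is.null(rownames(q))) rownames(q)
             else seq_len(nrow(q)),
             label = as.character(pred),
             confidence = attr(pred, "prob"),
             stringsAsFactors = FALSE)
}

#' Dosage grouping robust to transgene probe dropout
#'
#' Cells with transgene signal above `detection_floor` are grouped directly
#' with [dosage_cluster()]; the remaining (dropout) cells are annotated by
#' [transfer_labels()] from a labeled reference. The combined table records
#' the provenance of every label (`direct` or `transferred`).
#'
#' @param query normalized genes x cells matrix (or SCE with `logcounts`).
#' @param transgene_gene row id of the transgene in `query`.
#' @param reference,ref_labels labeled reference for the transfer arm
#'   (required only when dropout cells exist).
#' @param detection_floor normalized-signal floor; strictly greater counts as
#'   detected (default 0).
#' @param k,linkage passed to [dosage_cluster()].
#' @param n_pcs,k_neighbors passed to [transfer_labels()].
#' @return data.frame(cell_id, label, provenance, confidence); direct labels
#'   have confidence 1.
#' @export
dropout_aware_grouping <- function(query, transgene_gene,
                                   reference = NULL, ref_labels = NULL,
                                   detection_floor = 0, k = 3,
                                   linkage = "complete", n_pcs = 30,
                                   k_neighbors = 15) {
  m <- .get_logcounts(query)
  if (!transgene_gene %in% rownames(m))
    stop("transgene gene ", transgene_gene, " not found in query")
  vals <- as.numeric(m[transgene_gene, ])
  names(vals) <- colnames(m)
  detected <- vals > detection_floor
  out <- data.frame(cell_id = colnames(m), label = NA_character_,
                    provenance = NA_character_, confidence = NA_real_,
                    stringsAsFactors = FALSE)
  if (any(detected)) {
    dl <- dosage_cluster(vals[detected], k = k, linkage = linkage)
    out$label[detected] <- as.character(dl$labels)
    out$provenance[detected] <- "direct"
    out$confidence[detected] <- 1
  }
  if (any(!detected)) {
    if (is.null(reference) || is.null(ref_labels))
      stop("dropout cells present but no labeled reference supplied")
    # the transgene probe is the dropout artifact: reference cells carry
    # signal there and dropout cells cannot, so it is excluded from the
    # transfer feature space
    refm <- .get_logcounts(reference)
    refm <- refm[setdiff(rownames(refm), transgene_gene), , drop = FALSE]
    tr <- transfer_labels(refm, ref_labels,
                          m[setdiff(rownames(m), transgene_gene),
                            !detected, drop = FALSE],
                          n_pcs = n_pcs, k_neighbors = k_neighbors)
    out$label[!detected] <- tr$label
    out$provenance[!detected] <- "transferred"
    out$confidence[!detected] <- tr$confidence
  }
  out
}
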