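test_that("dosage clustering separates three well-spaced value blocks", {
  v <- setNames(c(0, 0, 0, 5, 5, 10, 10), paste0("c", 1:7))
  dl <- dosage_cluster(v, k = 3)
  expect_equal(as.character(dl$labels[1:3]), rep("low", 3))
  expect_equal(as.character(dl$labels[4:5]), rep("intermediate", 2))
  expect_equal(as.character(dl$labels[6:7]), rep("high", 2))
  expect_equal(unname(dl$group_means), c(0, 5, 10))
})

test_that("dosage clustering rejects inputs with fewer distinct values than k", {
  expect_error(dosage_cluster(rep(3, 10), k = 3), "distinct")
  expect_error(dosage_cluster(c(1, 1, 2, 2), k = 3), "reduce k")
})

test_that("tie-compressed clustering equals the naive full-distance oracle", {
  set.seed(61)
  for (i in 1:15) {
    n <- sample(50:500, 1)
    v <- rnbinom(n, size = 2, mu = sample(3:30, 1)) +
      sample(c(0, 0.5), n, replace = TRUE)
    if (length(unique(v)) < 3) next
    fast <- dosage_cluster(v, k = 3)$labels
    naive <- cutree(hclust(dist(v), method = "complete"), k = 3)
    expect_equal(adjusted_rand_index(as.character(fast), naive), 1)
  }
})

test_that("dosage clustering is invariant to cell permutation and value shifts", {
  set.seed(62)
  v <- setNames(c(rnorm(40, 0, 0.1), rnorm(40, 5, 0.1), rnorm(40, 10, 0.1)),
                paste0("c", 1:120))
  base <- dosage_cluster(v)$labels
  perm <- sample(names(v))
  lab_perm <- dosage_cluster(v[perm])$labels
  expect_equal(as.character(lab_perm[names(v)]), as.character(base))
  shifted <- dosage_cluster(v + 100)$labels
  expect_equal(as.character(shifted), as.character(base))
})

test_that("group naming orders by ascending marker mean and is idempotent", {
  lab <- c(1, 1, 2, 2, 3, 3)
  marker <- c(7.1, 7.1, 0.2, 0.2, 3.3, 3.3)
  named <- name_groups(lab, marker)
  expect_equal(as.character(named$labels),
               c("high", "high", "low", "low",
                 "intermediate", "intermediate"))
  expect_equal(unname(named$group_means), c(0.2, 3.3, 7.1))
  again <- name_groups(named$labels, marker)
  expect_equal(as.character(again$labels), as.character(named$labels))
})

test_that("tied group means break by group size with a message", {
  lab <- c("a", "a", "a", "b", "b")
  marker <- c(2, 2, 2, 2, 2)
  expect_message(named <- name_groups(lab, marker), "tied")
  # larger group first in the ordering
  expect_equal(as.character(named$labels[1]), "group1")
})

# transfer tests use a richer planted program than the shared fixture so the
# expression space, not the transgene alone, carries the group structure
transfer_data <- local({
  sce <- gen_mosaic_counts(generator_config(
    n_cells = 1200, n_genes = 400, n_program_genes = 60,
    transgene_means = c(0, 10, 60), seed = 101))
  truth <- S4Vectors::metadata(sce)$truth
  norm <- lognormalize(SummarizedExperiment::assay(sce))
  list(norm = norm, lab = truth$dosage_label[colnames(norm)])
})

test_that("label transfer recovers labels of held-out and duplicated cells", {
  lab <- transfer_data$lab
  set.seed(63)
  hold <- sample(ncol(transfer_data$norm), round(0.3 * ncol(transfer_data$norm)))
  ref <- as.matrix(transfer_data$norm[, -hold])
  qry <- as.matrix(transfer_data$norm[, hold])
  tr <- transfer_labels(ref, lab[-hold], qry)
  expect_gte(mean(tr$label == lab[hold]), 0.9)
  expect_true(all(tr$confidence >= 1 / 3 - 1e-9 & tr$confidence <= 1))
  # a query duplicating a reference cell with k = 1 returns its label exactly
  one <- transfer_labels(ref, lab[-hold], ref[, 5, drop = FALSE],
                         k_neighbors = 1)
  expect_equal(one$label, as.character(lab[-hold][5]))
  expect_equal(one$confidence, 1)
  # self-transfer sanity
  self <- transfer_labels(ref, lab[-hold], ref, k_neighbors = 15)
  expect_gte(mean(self$label == lab[-hold]), 0.95)
  expect_error(transfer_labels(ref, lab[-hold],
                               matrix(1, 2, 2, dimnames = list(c("x", "y"), NULL))),
               "no shared genes")
})

test_that("dropout-aware grouping reduces to direct clustering when all detected", {
  dl <- dosage_cluster(fix$tg)
  res <- dropout_aware_grouping(fix$norm, fix$truth$transgene_gene_id,
                                detection_floor = -1)
  expect_true(all(res$provenance == "direct"))
  expect_equal(res$label, as.character(dl$labels[res$cell_id]))
})

test_that("dropout-aware grouping transfers everything when nothing is detected", {
  qn <- as.matrix(fix$norm[, 1:50])
  qn[fix$truth$transgene_gene_id, ] <- 0
  lab <- fix$truth$dosage_label[colnames(fix$norm)]
  res <- dropout_aware_grouping(qn, fix$truth$transgene_gene_id,
                                reference = fix$norm, ref_labels = lab)
  expect_true(all(res$provenance == "transferred"))
  expect_error(dropout_aware_grouping(qn, fix$truth$transgene_gene_id),
               "no labeled reference")
})

test_that("dropout-aware grouping recovers planted groups under heavy dropout", {
  # one generated culture split into a labeled reference and a query batch
  # (same baseline means, same planted program), dropout planted in the query
  sce <- gen_mosaic_counts(generator_config(
    n_cells = 1800, n_genes = 400, n_program_genes = 60, seed = 202))
  truth <- S4Vectors::metadata(sce)$truth
  set.seed(204)
  ref_cells <- sample(colnames(sce), 1300)
  qry_cells <- setdiff(colnames(sce), ref_cells)
  counts <- as.matrix(SummarizedExperiment::assay(sce))
  ref_norm <- lognormalize(counts[, ref_cells])
  # plant 80% transgene dropout in the query high group
  qc <- counts[, qry_cells]
  hi <- which(truth$dosage_label[qry_cells] == "high")
  drop <- sample(hi, round(0.8 * length(hi)))
  qc[truth$transgene_gene_id, drop] <- 0
  qn <- lognormalize(qc)
  res <- dropout_aware_grouping(
    qn, truth$transgene_gene_id,
    reference = ref_norm,
    ref_labels = truth$dosage_label[ref_cells])
  ari <- adjusted_rand_index(res$label, truth$dosage_label[res$cell_id])
  expect_gte(ari, 0.8)
  expect_true(all(res$provenance[match(colnames(qc)[drop],
                                       res$cell_id)] == "transferred"))
})

test_that("adjusted Rand index agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(65)
  for (i in 1:10) {
    a <- sample(3, 60, replace = TRUE)
    b <- sample(4, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
})
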