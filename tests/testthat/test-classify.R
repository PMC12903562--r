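# 3-class linearly separable toy: 300 cells, 10 genes
separable_toy <- function(seed = 9, n = 300, noise = 0.2) {
  set.seed(seed)
  lab <- sample(c("low", "intermediate", "high"), n, replace = TRUE)
  mu <- cbind(low = c(rep(0, 5), rep(2, 5)),
              intermediate = rep(1, 10),
              high = c(rep(2, 5), rep(0, 5)))
  X <- sapply(seq_len(n), function(i) rnorm(10, mu[, lab[i]], noise))
  dimnames(X) <- list(paste0("g", 1:10), paste0("c", seq_len(n)))
  list(X = X, lab = lab)
}

test_that("the MLP reaches perfect validation accuracy on a separable toy", {
  toy <- separable_toy()
  m <- train_mlp(toy$X, toy$lab, seed = 1)
  expect_equal(m$validation_accuracy, 1.0)
  expect_lt(m$final_loss, m$initial_loss)
  # confusion matrix is diagonal
  expect_equal(sum(diag(m$validation_confusion)), sum(m$validation_confusion))
})

test_that("permuted labels train to chance-level accuracy", {
  toy <- separable_toy()
  set.seed(2)
  perm <- sample(toy$lab)
  m <- train_mlp(toy$X, perm, epochs = 100, seed = 2)
  prior <- max(table(perm)) / length(perm)
  expect_lt(abs(m$validation_accuracy - prior), 0.1)
})

test_that("training is deterministic under a fixed seed", {
  toy <- separable_toy()
  m1 <- train_mlp(toy$X, toy$lab, epochs = 20, seed = 5)
  m2 <- train_mlp(toy$X, toy$lab, epochs = 20, seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$train_idx, m2$train_idx)
})

test_that("softmax probabilities are normalized; zero weights give uniform output", {
  toy <- separable_toy()
  m <- train_mlp(toy$X, toy$lab, epochs = 5, seed = 3)
  pr <- predict(m, toy$X)$prob
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  m0 <- m
  m0$weights <- lapply(m0$weights, function(w) w * 0)
  m0$biases <- lapply(m0$biases, function(b) b * 0)
  pr0 <- predict(m0, toy$X)$prob
  expect_true(all(abs(pr0 - 1 / 3) < 1e-12))
})

test_that("prediction on training data beats the validation split on the toy", {
  toy <- separable_toy()
  m <- train_mlp(toy$X, toy$lab, seed = 1)
  tr <- predict(m, toy$X[, m$train_idx], truth = toy$lab[m$train_idx])
  expect_gte(tr$accuracy, m$validation_accuracy)
})

test_that("prediction errors on missing features, naming them", {
  toy <- separable_toy()
  m <- train_mlp(toy$X, toy$lab, epochs = 5, seed = 1)
  expect_error(predict(m, toy$X[1:8, ]), "g10|g9")
})

test_that("classifier-gene selection sizes follow the fraction arithmetic", {
  toy <- separable_toy()
  m <- train_mlp(toy$X, toy$lab, epochs = 5, seed = 1)
  # forge a wide model to check the fraction arithmetic at transcriptome scale
  wide <- m
  set.seed(4)
  wide$features <- sprintf("g%05d", 1:29040)
  wide$w1_init <- matrix(rnorm(29040 * 16, sd = 0.01), 29040, 16)
  wide$weights[[1]] <- wide$w1_init + matrix(rnorm(29040 * 16, sd = 0.01),
                                             29040, 16)
  sel <- extract_classifier_genes(wide, fraction = 0.05)
  expect_equal(length(sel$selected), 1452)
  expect_equal(sel$selected, sel$ranking$gene[1:1452])
})

test_that("a gene with untouched zero first-layer weights ranks last", {
  toy <- separable_toy()
  m <- train_mlp(toy$X, toy$lab, epochs = 5, seed = 1)
  m$weights[[1]][3, ] <- 0
  m$w1_init[3, ] <- 0
  for (meth in c("weight_delta_l2", "input_weight_l2")) {
    r <- extract_classifier_genes(m, fraction = 0.2, method = meth)$ranking
    expect_equal(r$gene[nrow(r)], "g3")
    expect_equal(r$importance[nrow(r)], 0)
  }
  expect_error(extract_classifier_genes(m, method = "permutation"),
               "validation data")
})

test_that("importance methods broadly agree on informative features", {
  # sparse planted program (10 informative genes of 200) so permutation
  # importance is not diluted by redundancy; median overlap over 5 seeds
  ov <- sapply(1:5, function(s) {
    sce <- gen_mosaic_counts(generator_config(
      n_cells = 800, n_genes = 200, n_program_genes = 10,
      transgene_means = c(0, 10, 60), seed = 300 + s))
    truth <- S4Vectors::metadata(sce)$truth
    norm <- lognormalize(SummarizedExperiment::assay(sce))
    lab <- truth$dosage_label[colnames(norm)]
    m <- train_mlp(norm, lab, epochs = 60, seed = s)
    perm <- extract_classifier_genes(m, 0.05, "permutation",
                                     X = norm, labels = lab,
                                     seed = s)$selected
    vapply(c("weight_delta_l2", "input_weight_l2"), function(meth) {
      sel <- extract_classifier_genes(m, 0.05, meth)$selected
      length(intersect(sel, perm)) / length(sel)
    }, numeric(1))
  })
  expect_gte(median(ov["weight_delta_l2", ]), 0.5)
  expect_gte(median(ov["input_weight_l2", ]), 0.5)
})

test_that("cohort projection recovers planted tumor/healthy classes", {
  cohort <- gen_cohort(n_samples_per_class = 8, n_cells_per_sample = 150,
                       n_genes = 300, n_program_genes = 50,
                       program_log2fc = 1.5, seed = 71)
  truth <- S4Vectors::metadata(cohort)$truth
  grouping <- cohort_group(cohort, truth$program_genes, k = 2)
  cls <- sub("_s\\d+$", "", names(grouping$sample_groups))
  expect_gte(adjusted_rand_index(as.character(grouping$sample_groups), cls), 0.8)
  # composition shift: fibroblast share higher in the high-marker group
  expect_gt(grouping$proportions["group2", "fibroblast"],
            grouping$proportions["group1", "fibroblast"])
  # group marker means ascend by construction
  expect_true(all(diff(grouping$group_marker_means) > 0))
  expect_true(all(abs(rowSums(grouping$proportions) - 1) < 1e-9))
})

test_that("cohort projection validates its inputs", {
  cohort <- gen_cohort(n_samples_per_class = 2, n_cells_per_sample = 60,
                       n_genes = 100, n_program_genes = 20, seed = 72)
  truth <- S4Vectors::metadata(cohort)$truth
  expect_error(cohort_group(cohort, c("absent1", "absent2")),
               "no classifier gene")
  expect_error(cohort_group(cohort, truth$program_genes, k = 5),
               "cannot form")
})

test_that("composition comparison flags planted shifts and not null ones", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2,
                dimnames = list(c("g1", "g2"), c("ductal", "fibroblast")))
  res <- composition_compare(tab)
  expect_lt(res$overall$p_value, 0.01)

  # identical composition: no BH-adjusted post-hoc passes
  tab0 <- matrix(c(200, 200, 100, 100, 50, 50), 2, 3,
                 dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  res0 <- composition_compare(tab0)
  expect_false(any(res0$per_celltype$p_adj < 0.05))

  cohort <- gen_cohort(n_samples_per_class = 20, n_cells_per_sample = 120,
                       n_genes = 80, n_program_genes = 15,
                       composition_shift = c(fibroblast = 1), seed = 73)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  tab2 <- table(cd$class, cd$celltype)
  res2 <- composition_compare(tab2)
  fib <- res2$per_celltype[res2$per_celltype$celltype == "fibroblast", ]
  expect_lt(fib$p_adj, 0.05)
})
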