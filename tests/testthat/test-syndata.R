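test_that("mosaic generator is byte-identical under a fixed seed", {
  cfg <- generator_config(n_cells = 500, n_genes = 150,
                          n_program_genes = 30, seed = 7)
  a <- gen_mosaic_counts(cfg)
  b <- gen_mosaic_counts(cfg)
  expect_identical(SummarizedExperiment::assay(a), SummarizedExperiment::assay(b))
  expect_identical(S4Vectors::metadata(a)$truth, S4Vectors::metadata(b)$truth)
})

test_that("low-group transgene detection matches the configured sparse fraction", {
  cfg <- generator_config(n_cells = 4000, n_genes = 100,
                          n_program_genes = 20,
                          transgene_means = c(0, 8, 40),
                          low_detection_fraction = 0.15, seed = 11)
  sce <- gen_mosaic_counts(cfg)
  truth <- S4Vectors::metadata(sce)$truth
  tg <- as.numeric(SummarizedExperiment::assay(sce)["KRASG12D", ])
  low <- truth$dosage_label == "low"
  frac <- mean(tg[low] > 0)
  tol <- 3 * sqrt(0.15 * 0.85 / sum(low))
  expect_lt(abs(frac - 0.15), tol)
  # detected low cells carry only 1-2 stray reads
  expect_true(all(tg[low] %in% 0:2))
})

test_that("degenerate single-group config yields an all-zero transgene column", {
  cfg <- generator_config(n_cells = 300, n_genes = 50,
                          n_program_genes = 10,
                          group_proportions = c(1, 0, 0),
                          low_detection_fraction = 0, seed = 1)
  sce <- gen_mosaic_counts(cfg)
  expect_true(all(SummarizedExperiment::assay(sce)["KRASG12D", ] == 0))
  expect_true(all(S4Vectors::metadata(sce)$truth$dosage_label == "low"))
})

test_that("generator config validation rejects inconsistent settings", {
  expect_error(generator_config(n_program_genes = 300, n_genes = 100),
               "invalid config")
  expect_error(generator_config(group_proportions = c(0.5, 0.5, 0.5)),
               "sum")
  expect_error(generator_config(nb_dispersion = 0), "positive")
})

test_that("effect sizes are zero off-program and dosage-ordered on-program", {
  truth <- fix$truth
  eff <- truth$effect_log2fc
  off <- setdiff(rownames(eff), truth$program_genes)
  expect_true(all(eff[off, ] == 0))
  expect_true(all(eff[truth$program_genes, "high"] ==
                    2 * eff[truth$program_genes, "intermediate"]))
  expect_true(all(eff[, "low"] == 0))
})

test_that("planted program genes top a naive mean-difference ranking (AUC >= 0.95)", {
  truth <- fix$truth
  lab <- truth$dosage_label[colnames(fix$norm)]
  hi <- lab == "high"; lo <- lab == "low"
  stat <- abs(rowMeans(fix$norm[, hi, drop = FALSE]) -
                rowMeans(fix$norm[, lo, drop = FALSE]))
  genes <- setdiff(rownames(fix$norm), truth$transgene_gene_id)
  auc <- auc_of(stat[genes], genes %in% truth$program_genes)
  expect_gte(auc, 0.95)
})

test_that("unit-efficiency single-probe matrix reproduces the gene matrix", {
  pm <- gen_probe_counts(fix$counts[1:30, 1:40], probes_per_gene = 1,
                         efficiencies = 1, seed = 2)
  expect_equal(unname(as.matrix(SummarizedExperiment::assay(pm))),
               unname(as.matrix(fix$counts[1:30, 1:40])))
})

test_that("per-probe means follow the binomial thinning efficiencies", {
  genes <- matrix(10L, nrow = 2, ncol = 1500,
                  dimnames = list(c("gA", "gB"), paste0("c", 1:1500)))
  pm <- gen_probe_counts(genes, probes_per_gene = 3,
                         efficiencies = c(1, 0.01, 0.001), seed = 3)
  mu <- Matrix::rowMeans(SummarizedExperiment::assay(pm))
  expect_true(all(mu[c(1, 4)] == 10))           # efficiency 1 is lossless
  expect_true(mu[1] > mu[2] && mu[2] > mu[3])
  expect_error(gen_probe_counts(genes, 2, c(1, 1.2)), "\\(0, 1\\]")
  expect_error(gen_probe_counts(genes, 2, c(0, 1)), "\\(0, 1\\]")
})

test_that("probe split + filter + aggregation round-trips within sampling error", {
  genes <- fix$counts[1:50, 1:300]
  pm <- gen_probe_counts(genes, probes_per_gene = 2,
                         efficiencies = c(1, 1), seed = 4)
  flt <- filter_probes(pm)
  agg <- aggregate_probes(flt$probes)
  # equal unit efficiencies: exact reproduction
  expect_equal(as.matrix(SummarizedExperiment::assay(agg))[rownames(genes), ],
               as.matrix(genes))
  # unequal efficiencies: weak probe filtered out, strong probe carries through
  pm2 <- gen_probe_counts(genes, probes_per_gene = 2,
                          efficiencies = c(1, 0.01), seed = 5)
  flt2 <- filter_probes(pm2)
  agg2 <- aggregate_probes(flt2$probes)
  mad <- mean(abs(as.matrix(SummarizedExperiment::assay(agg2))[rownames(genes), ] -
                    as.matrix(genes)))
  expect_lt(mad, 0.05)
})

test_that("cohort generator plants composition shifts and is reproducible", {
  null_sh <- gen_cohort(n_samples_per_class = 20, n_cells_per_sample = 150,
                        n_genes = 60, n_program_genes = 10,
                        composition_shift = c(fibroblast = 0), seed = 9)
  cd <- SummarizedExperiment::colData(null_sh)
  prop_by <- function(x, ct) {
    tapply(x$celltype == ct, x$class, mean)
  }
  p0 <- prop_by(as.data.frame(cd), "fibroblast")
  expect_lt(abs(p0["tumor"] - p0["healthy"]), 0.04)

  sh <- gen_cohort(n_samples_per_class = 20, n_cells_per_sample = 150,
                   n_genes = 60, n_program_genes = 10,
                   composition_shift = c(fibroblast = 1), seed = 9)
  p1 <- prop_by(as.data.frame(SummarizedExperiment::colData(sh)), "fibroblast")
  expect_gt(p1["tumor"], p1["healthy"])

  again <- gen_cohort(n_samples_per_class = 20, n_cells_per_sample = 150,
                      n_genes = 60, n_program_genes = 10,
                      composition_shift = c(fibroblast = 1), seed = 9)
  expect_identical(SummarizedExperiment::assay(sh),
                   SummarizedExperiment::assay(again))
  expect_error(gen_cohort(celltypes = character(0)), "non-empty")
  expect_error(gen_cohort(celltypes = c("fibroblast", "tcell")), "ductal")
})

test_that("spot-image generator honors marker fraction and spot settings", {
  im <- gen_spot_image(n_cells = 100, marker_pos_fraction = 0.5, seed = 21)
  n_pos <- sum(im$truth$cells$marker_pos)
  expect_lt(abs(n_pos - 50), 3 * sqrt(100 * 0.25))
  expect_equal(nrow(im$truth$cells), 100)
  expect_equal(sum(im$truth$cells$n_spots), nrow(im$truth$spots))

  blank <- gen_spot_image(n_cells = 20, spots_per_pos_cell = 0,
                          noise_sd = 0.02, seed = 22)
  expect_lt(max(blank$image[, , "spots"]), 0.2)  # noise only
  expect_equal(nrow(blank$truth$spots), 0)

  expect_error(gen_spot_image(n_cells = 100, img_size = 100), "too small")
  rep1 <- gen_spot_image(n_cells = 30, seed = 5)
  rep2 <- gen_spot_image(n_cells = 30, seed = 5)
  expect_identical(rep1$image, rep2$image)
})

test_that("cyst cohort generator hits grade sizes, medians and T1a share", {
  co <- gen_cyst_cohort(seed = 1)
  expect_equal(nrow(co), 80)
  expect_equal(as.numeric(table(co$grade)), c(27, 25, 28))
  expect_equal(sum(co$t_stage == "T1a", na.rm = TRUE), 8)
  expect_true(all(is.na(co$t_stage[co$grade != "IC"])))

  big <- gen_cyst_cohort(n_per_grade = c(200, 200, 200), seed = 2)
  med <- tapply(big$tnfa_pg_ml, big$grade, median)
  expect_true(all(abs(med / c(3.21, 6.35, 11.65) - 1) < 0.25))

  det <- gen_cyst_cohort(log_sd = 0, seed = 3)
  expect_true(all(abs(det$tnfa_pg_ml[det$grade == "HGD"] - 6.35) < 1e-12))
  expect_error(gen_cyst_cohort(medians_pg_ml = c(0, 1, 2)), "positive")
})

test_that("MTX round trip preserves the count matrix and ids", {
  dir <- tempfile("mtx")
  write_mtx(fix$counts[1:25, 1:30], dir)
  back <- read_mtx(dir)
  expect_equal(as.matrix(SummarizedExperiment::assay(back)),
               as.matrix(fix$counts[1:25, 1:30]))
})
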