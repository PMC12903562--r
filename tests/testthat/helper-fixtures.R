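# Shared small-scale fixtures, generated once per test run.

fix <- local({
  # transgene means scaled down with the gene space so the transgene stays
  # a realistic ~10% of the library in high cells
  sce <- gen_mosaic_counts(generator_config(
    n_cells = 1200, n_genes = 400, n_program_genes = 20,
    transgene_means = c(0, 10, 60), seed = 101))
  truth <- S4Vectors::metadata(sce)$truth
  counts <- SummarizedExperiment::assay(sce, "counts")
  norm <- lognormalize(counts)
  tg <- setNames(as.numeric(norm[truth$transgene_gene_id, ]), colnames(norm))
  list(sce = sce, truth = truth, counts = counts, norm = norm, tg = tg)
})

# area-under-curve of a score separating a binary truth (rank-sum identity)
auc_of <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# independent one-tailed Mann-Whitney p by direct enumeration of U counts
enum_mw_p <- function(a, b, alternative = "greater") {
  u_of <- function(x, y) sum(outer(y, x, ">")) + 0.5 * sum(outer(y, x, "=="))
  vals <- c(a, b)
  nb <- length(b)
  combos <- combn(length(vals), nb)
  u_obs <- u_of(a, b)
  u_all <- apply(combos, 2, function(j) u_of(vals[-j], vals[j]))
  if (alternative == "greater") mean(u_all >= u_obs - 1e-9)
  else mean(u_all <= u_obs + 1e-9)
}
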