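#' Default pipeline configuration
#'
#' Nested list of every tunable stage parameter with the package defaults.
#' The synthetic-data block mirrors [generator_config()]; QC defaults are
#' permissive because the synthetic gene space has no mitochondrial genes and
#' a smaller per-cell gene count than a real transcriptome (set `preset` to
#' `"time-series"`, `"coculture"` or `"cohort"` to apply the corresponding
#' real-data thresholds).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    preset = "none",
    syndata = list(n_cells = 6000, n_genes = 2000,
                   group_proportions = c(0.40, 0.35, 0.25),
                   transgene_means = c(0, 40, 400),
                   nb_dispersion = 15,
                   n_program_genes = 100,
                   program_effect_mean = 2.5,
                   program_effect_sd = 0.25,
                   low_detection_fraction = 0.15),
    qc = list(max_mito_fraction = 1.0, min_genes = 0, max_genes = NULL,
              min_cells_per_gene = 3, probe_threshold = 0.2),
    scoring = list(scale_factor = 10000, n_bins = 24, n_ctrl = 100),
    stratify = list(k = 3, linkage = "complete"),
    classify = list(epochs = 200, train_fraction = 0.65,
                    learning_rate = 0.01, batch_size = 32,
                    hidden_units = 16, fraction = 0.05),
    cohort = list(n_samples_per_class = 12, n_cells_per_sample = 250,
                  marker_gene = "KRAS")
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a mapping")
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys with the
#' offending key named, fills every missing key from [default_config()], and
#' sanity-checks cross-stage constraints before any compute.
#'
#' @param config path to a YAML file, a configuration list, or NULL (pure
#'   defaults).
#' @return normalized configuration list (class `kdn_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  cfg <- .merge_config(default_config(), config)
  if (!cfg$preset %in% c("none", "time-series", "coculture", "cohort"))
    stop("unknown preset: ", cfg$preset)
  if (cfg$preset != "none") {
    thr <- qc_preset(cfg$preset)
    cfg$qc[names(unclass(thr))] <- unclass(thr)
  }
  if (cfg$stratify$k < 2)
    stop("stratify.k must be >= 2 (got ", cfg$stratify$k, ")")
  validate_generator_config(c(cfg$syndata, seed = cfg$seed))
  structure(cfg, class = "kdn_config")
}

#' Run the end-to-end synthetic demonstration pipeline
#'
#' Sequences the full analysis on generated data: simulate the mosaic count
#' matrix, QC-filter, log-normalize, stratify cells by transgene dosage,
#' train the MLP classifier, extract classifier genes and score their
#' recovery of the planted program, simulate and project an external cohort
#' with composition statistics, and score the planted program as a gene
#' module per dosage group. Writes a machine-readable JSON report plus CSV
#' artifacts into `out_dir`; the global seed fully determines every
#' stochastic stage.
#'
#' @param config anything [validate_config()] accepts.
#' @param out_dir output directory; NULL skips writing artifacts.
#' @return the report list (also serialized to `out_dir/report.json`).
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- validate_config(config)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  sce <- stage("simulate", gen_mosaic_counts(
    generator_config(n_cells = cfg$syndata$n_cells,
                     n_genes = cfg$syndata$n_genes,
                     group_proportions = cfg$syndata$group_proportions,
                     transgene_means = cfg$syndata$transgene_means,
                     nb_dispersion = cfg$syndata$nb_dispersion,
                     n_program_genes = cfg$syndata$n_program_genes,
                     program_effect_mean = cfg$syndata$program_effect_mean,
                     program_effect_sd = cfg$syndata$program_effect_sd,
                     low_detection_fraction = cfg$syndata$low_detection_fraction,
                     seed = cfg$seed)))
  truth <- S4Vectors::metadata(sce)$truth

  sce <- stage("qc", {
    thr <- qc_thresholds(cfg$qc$max_mito_fraction, cfg$qc$min_genes,
                         cfg$qc$max_genes, cfg$qc$min_cells_per_gene)
    out <- suppressWarnings(filter_cells(sce, thr))
    filter_genes(out, cfg$qc$min_cells_per_gene)
  })

  norm <- stage("normalize",
                lognormalize(.get_counts(sce), cfg$scoring$scale_factor))

  labels <- stage("stratify", dosage_cluster(
    setNames(as.numeric(norm[truth$transgene_gene_id, ]), colnames(norm)),
    k = cfg$stratify$k, linkage = cfg$stratify$linkage))
  planted <- truth$dosage_label[colnames(norm)]
  ari <- adjusted_rand_index(as.character(labels$labels), planted)

  model <- stage("train", train_mlp(
    norm, labels$labels, epochs = cfg$classify$epochs,
    train_fraction = cfg$classify$train_fraction,
    learning_rate = cfg$classify$learning_rate,
    batch_size = cfg$classify$batch_size,
    hidden_units = cfg$classify$hidden_units, seed = cfg$seed))

  genes <- stage("classifier-genes",
                 extract_classifier_genes(model, cfg$classify$fraction))
  program_present <- intersect(truth$program_genes, rownames(norm))
  recovery <- mean(program_present %in% genes$selected)

  cohort_res <- stage("project", {
    cohort <- gen_cohort(n_samples_per_class = cfg$cohort$n_samples_per_class,
                         n_cells_per_sample = cfg$cohort$n_cells_per_sample,
                         n_genes = cfg$syndata$n_genes,
                         program_genes = program_present,
                         seed = cfg$seed + 1L)
    grouping <- cohort_group(cohort, genes,
                             marker_gene = cfg$cohort$marker_gene,
                             k = cfg$stratify$k)
    list(grouping = grouping, compare = composition_compare(grouping))
  })

  score_means <- stage("score", {
    sc <- module_score(norm, program_present, n_bins = cfg$scoring$n_bins,
                       n_ctrl = cfg$scoring$n_ctrl, seed = cfg$seed)
    tapply(sc, labels$labels[names(sc)], mean)
  })

  report <- list(
    seed = cfg$seed,
    n_cells = ncol(norm), n_genes = nrow(norm),
    stratify_ari = ari,
    group_means = as.list(labels$group_means),
    validation_accuracy = model$validation_accuracy,
    confusion = as.data.frame.matrix(unclass(model$validation_confusion)),
    classifier_recovery = recovery,
    n_classifier_genes = length(genes$selected),
    cohort_proportions = as.data.frame.matrix(
      unclass(cohort_res$grouping$proportions)),
    composition_overall_p = cohort_res$compare$overall$p_value,
    program_module_score_by_group = as.list(score_means))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
    write.csv(data.frame(cell_id = names(labels$labels),
                         label = as.character(labels$labels)),
              file.path(out_dir, "dosage_labels.csv"), row.names = FALSE)
    write.csv(genes$ranking, file.path(out_dir, "classifier_genes.csv"),
              row.names = FALSE)
  }
  invisible(report)
}
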