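#' Generator configuration for the mosaic single-cell count simulator
#'
#' Bundles and validates every knob of [gen_mosaic_counts()]. The defaults
#' define the package's reference simulation: a mosaic culture in which three
#' subpopulations carry graded expression of an oncogenic transgene
#' (low / intermediate / high dosage), plus a set of "niche program" genes
#' whose expression shifts with dosage. Counts are negative binomial
#' (gamma-Poisson) with a single shared dispersion; this is a generative
#' stand-in, not an estimate from any real data set.
#'
#' @param n_cells number of cells.
#' @param n_genes number of endogenous genes (the transgene is added on top).
#' @param group_proportions length-3 vector of expected group proportions
#'   (low, intermediate, high); must sum to 1.
#' @param transgene_means length-3 vector of mean transgene counts per group.
#'   The low-group entry is retained for ordering only: low-group cells follow
#'   the sparse detection rule below instead of a negative-binomial draw.
#' @param nb_dispersion shared negative-binomial size parameter (larger =
#'   closer to Poisson).
#' @param n_program_genes number of dosage-responsive program genes.
#' @param program_effect_mean mean high-group effect, log2 units.
#' @param program_effect_sd SD of the per-gene high-group effect, log2 units.
#' @param low_detection_fraction fraction of low-group cells that receive 1-2
#'   stray transgene reads (the remainder get exactly 0), mirroring the sparse
#'   detection motif of low-dosage clusters.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `kdn_generator_config` list.
#' @export
generator_config <- function(n_cells = 6000, n_genes = 2000,
                             group_proportions = c(0.40, 0.35, 0.25),
                             transgene_means = c(0, 40, 400),
                             nb_dispersion = 15,
                             n_program_genes = 100,
                             program_effect_mean = 2.5,
                             program_effect_sd = 0.25,
                             low_detection_fraction = 0.15,
                             seed = 1L) {
  cfg <- list(n_cells = n_cells, n_genes = n_genes,
              group_proportions = group_proportions,
              transgene_means = transgene_means,
              nb_dispersion = nb_dispersion,
              n_program_genes = n_program_genes,
              program_effect_mean = program_effect_mean,
              program_effect_sd = program_effect_sd,
              low_detection_fraction = low_detection_fraction,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "kdn_generator_config")
}

#' @rdname generator_config
#' @param cfg a configuration list to validate.
#' @export
validate_generator_config <- function(cfg) {
  if (!.is_count(cfg$n_cells) || cfg$n_cells < 1) stop("n_cells must be a positive count")
  if (!.is_count(cfg$n_genes) || cfg$n_genes < 1) stop("n_genes must be a positive count")
  if (length(cfg$group_proportions) != 3 ||
      abs(sum(cfg$group_proportions) - 1) > 1e-12 ||
      any(cfg$group_proportions < 0))
    stop("group_proportions must be 3 non-negative values summing to 1")
  if (length(cfg$transgene_means) != 3 || any(cfg$transgene_means < 0))
    stop("transgene_means must be 3 non-negative values")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (!.is_count(cfg$n_program_genes)) stop("n_program_genes must be a count")
  if (cfg$n_program_genes > cfg$n_genes)
    stop("invalid config: n_program_genes (", cfg$n_program_genes,
         ") exceeds n_genes (", cfg$n_genes, ")")
  if (cfg$low_detection_fraction < 0 || cfg$low_detection_fraction > 1)
    stop("low_detection_fraction must be in [0, 1]")
  invisible(cfg)
}

.DOSAGE_LEVELS <- c("low", "intermediate", "high")

#' Simulate a mosaic transgene-dosage single-cell count matrix
#'
#' Draws a cells-within-three-dosage-groups count matrix with planted ground
#' truth. Endogenous baseline means are log-normal across genes; counts are
#' negative binomial with the shared dispersion of `config`. Program genes
#' (sampled among genes with baseline mean at or above the median, i.e.
#' robustly expressed) are shifted multiplicatively by `2^effect`, with the
#' high-group effect drawn per gene from
#' `N(program_effect_mean, program_effect_sd)` and the intermediate-group
#' effect set to half of it. The transgene column follows the group means of
#' `config`, except in the low group where a configurable fraction of cells
#' receives 1-2 stray reads and the remainder exactly 0.
#'
#' @param config a [generator_config()].
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts` (genes x cells, sparse), `colData$dosage_label` (planted truth),
#'   rowData flags, and `metadata(sce)$truth` — a list with fields
#'   `dosage_label`, `program_genes`, `effect_log2fc` (genes x 3 matrix, zero
#'   off-program), and `transgene_gene_id`.
#' @export
gen_mosaic_counts <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_cells
  g <- config$n_genes

  labels <- factor(sample(.DOSAGE_LEVELS, n, replace = TRUE,
                          prob = config$group_proportions),
                   levels = .DOSAGE_LEVELS)

  gene_ids <- sprintf("gene%04d", seq_len(g))
  base_mu <- rlnorm(g, meanlog = 0, sdlog = 1)

  # program genes drawn among robustly expressed genes (top half by baseline
  # mean, widened if the config asks for more program genes than that)
  n_eligible <- max(config$n_program_genes, ceiling(g / 2))
  eligible <- order(base_mu, decreasing = TRUE)[seq_len(n_eligible)]
  program <- sort(sample(eligible, config$n_program_genes))
  eff_high <- rnorm(config$n_program_genes,
                    config$program_effect_mean, config$program_effect_sd)
  effect <- matrix(0, nrow = g, ncol = 3,
                   dimnames = list(gene_ids, .DOSAGE_LEVELS))
  effect[program, "high"] <- eff_high
  effect[program, "intermediate"] <- eff_high / 2

  counts <- matrix(0L, nrow = g, ncol = n)
  for (grp in .DOSAGE_LEVELS) {
    idx <- which(labels == grp)
    if (!length(idx)) next
    mu <- base_mu * 2^effect[, grp]
    counts[, idx] <- rnbinom(g * length(idx), size = config$nb_dispersion,
                             mu = mu)
  }

  # transgene row: NB in intermediate/high, sparse detection rule in low
  tg <- integer(n)
  for (k in 2:3) {
    idx <- which(labels == .DOSAGE_LEVELS[k])
    if (length(idx))
      tg[idx] <- rnbinom(length(idx), size = config$nb_dispersion,
                         mu = config$transgene_means[k])
  }
  low_idx <- which(labels == "low")
  if (length(low_idx) && config$low_detection_fraction > 0) {
    detected <- low_idx[runif(length(low_idx)) < config$low_detection_fraction]
    tg[detected] <- sample(1:2, length(detected), replace = TRUE)
  }

  mat <- rbind(counts, matrix(tg, nrow = 1))
  rownames(mat) <- c(gene_ids, "KRASG12D")
  colnames(mat) <- sprintf("cell%05d", seq_len(n))
  mat <- Matrix::Matrix(mat, sparse = TRUE)

  truth <- list(dosage_label = setNames(as.character(labels), colnames(mat)),
                program_genes = gene_ids[program],
                effect_log2fc = effect,
                transgene_gene_id = "KRASG12D")

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(dosage_label = labels,
                                   row.names = colnames(mat)),
    rowData = S4Vectors::DataFrame(
      is_program = rownames(mat) %in% truth$program_genes,
      is_transgene = rownames(mat) == "KRASG12D",
      row.names = rownames(mat)))
  S4Vectors::metadata(sce)$truth <- truth
  sce
}

#' Split gene-level counts into probe-level counts of unequal efficiency
#'
#' Emulates hybridization-probe chemistry in which several probes target one
#' gene and perform unequally: each probe's count is drawn independently as
#' `Binomial(gene count, efficiency)`. With a single probe of efficiency 1 the
#' probe matrix equals the gene matrix exactly.
#'
#' @param cells SingleCellExperiment or genes x cells integer matrix.
#' @param probes_per_gene probes per gene (>= 1).
#' @param efficiencies per-probe capture efficiency in (0, 1]; either length
#'   `probes_per_gene` (recycled across genes) or one value per probe row.
#' @param seed integer seed.
#' @return a SingleCellExperiment of probes x cells with
#'   `rowData(probe_id, gene)` providing the probe-to-gene map.
#' @export
gen_probe_counts <- function(cells, probes_per_gene = 3,
                             efficiencies = c(1, 0.5, 0.1), seed = 1L) {
  counts <- as.matrix(.get_counts(cells))
  .stopifnot_named(counts, "cells")
  if (!.is_count(probes_per_gene) || probes_per_gene < 1)
    stop("probes_per_gene must be >= 1")
  g <- nrow(counts); n <- ncol(counts)
  npr <- g * probes_per_gene
  if (length(efficiencies) == probes_per_gene) {
    eff <- rep(efficiencies, times = g)
  } else if (length(efficiencies) == npr) {
    eff <- efficiencies
  } else stop("efficiencies must have length probes_per_gene or one per probe")
  if (any(eff <= 0 | eff > 1)) stop("efficiencies must lie in (0, 1]")

  set.seed(as.integer(seed))
  gene_of <- rep(rownames(counts), each = probes_per_gene)
  probe_id <- paste0(gene_of, "-probe",
                     rep(seq_len(probes_per_gene), times = g))
  # expand genes to probe rows, then thin binomially
  expanded <- counts[rep(seq_len(g), each = probes_per_gene), , drop = FALSE]
  pm <- matrix(rbinom(npr * n, size = as.vector(expanded),
                      prob = rep(eff, times = n)),
               nrow = npr, dimnames = list(probe_id, colnames(counts)))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(pm, sparse = TRUE)),
    rowData = S4Vectors::DataFrame(probe_id = probe_id, gene = gene_of,
                                   row.names = probe_id))
}

#' Simulate a multi-sample labeled cohort with composition shifts
#'
#' Emulates an external tumor-versus-healthy cohort of single cells from
#' several samples with given cell-type labels. Tumor-class samples have their
#' cell-type composition tilted by per-cell-type log-odds, and their ductal
#' cells express the planted dosage program genes plus an elevated
#' transgene-homolog marker gene (`KRAS`).
#'
#' @param n_samples_per_class samples per class (classes `healthy`, `tumor`).
#' @param celltypes cell-type labels; must include `"ductal"`.
#' @param composition_shift named numeric log-odds added to tumor-class
#'   composition (names in `celltypes`); missing types shift 0.
#' @param n_cells_per_sample cells drawn per sample.
#' @param n_genes endogenous genes (ids shared with [gen_mosaic_counts()]).
#' @param program_genes character ids of genes induced in tumor ductal cells;
#'   default samples `n_program_genes` ids as the mosaic generator does.
#' @param n_program_genes used when `program_genes` is NULL.
#' @param program_log2fc induction of program genes in tumor ductal cells.
#' @param marker_log2fc induction of the `KRAS` marker in tumor ductal cells.
#' @param base_proportions baseline composition (recycled/normalized).
#' @param nb_dispersion shared NB size.
#' @param seed integer seed.
#' @return SingleCellExperiment with `colData(sample_id, class, celltype)` and
#'   `metadata()$truth` (program genes, shift, baseline composition).
#' @export
gen_cohort <- function(n_samples_per_class = 12,
                       celltypes = c("ductal", "fibroblast", "tcell",
                                     "macrophage", "endothelial"),
                       composition_shift = c(fibroblast = 1, tcell = 0.5),
                       n_cells_per_sample = 250,
                       n_genes = 2000,
                       program_genes = NULL,
                       n_program_genes = 100,
                       program_log2fc = 1,
                       marker_log2fc = 2,
                       base_proportions = c(0.45, 0.20, 0.15, 0.12, 0.08),
                       nb_dispersion = 15,
                       seed = 1L) {
  if (!length(celltypes)) stop("celltype list must be non-empty")
  if (!"ductal" %in% celltypes) stop("celltypes must include 'ductal'")
  if (n_samples_per_class < 1) stop("need >= 1 sample per class")
  set.seed(as.integer(seed))

  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  base_mu <- rlnorm(n_genes, 0, 1)
  if (is.null(program_genes)) {
    eligible <- which(base_mu >= median(base_mu))
    program_genes <- sort(gene_ids[sample(eligible, n_program_genes)])
  }
  prog_idx <- match(program_genes, gene_ids)
  if (anyNA(prog_idx)) stop("program_genes must be among the cohort gene ids")

  nt <- length(celltypes)
  p0 <- rep_len(base_proportions, nt); p0 <- p0 / sum(p0)
  names(p0) <- celltypes
  shift <- setNames(numeric(nt), celltypes)
  shift[names(composition_shift)] <- composition_shift
  p_tumor <- p0 * exp(shift); p_tumor <- p_tumor / sum(p_tumor)

  # mild cell-type identity markers so expression, not only labels, separates types
  pool <- setdiff(seq_len(n_genes), prog_idx)
  bs <- min(20, floor(length(pool) / nt))
  marker_block <- split(sample(pool, bs * nt), rep(celltypes, each = bs))

  classes <- c("healthy", "tumor")
  all_counts <- list(); cd <- list()
  for (cl in classes) {
    for (s in seq_len(n_samples_per_class)) {
      sample_id <- paste0(cl, "_s", s)
      props <- if (cl == "tumor") p_tumor else p0
      ct <- sample(celltypes, n_cells_per_sample, replace = TRUE, prob = props)
      mu <- matrix(base_mu, nrow = n_genes, ncol = n_cells_per_sample)
      for (tt in celltypes) {
        j <- which(ct == tt)
        if (length(j)) mu[marker_block[[tt]], j] <- mu[marker_block[[tt]], j] * 4
      }
      kras_mu <- rep(1, n_cells_per_sample)
      if (cl == "tumor") {
        j <- which(ct == "ductal")
        if (length(j)) {
          mu[prog_idx, j] <- mu[prog_idx, j] * 2^program_log2fc
          kras_mu[j] <- 2^marker_log2fc
        }
      }
      m <- matrix(rnbinom(n_genes * n_cells_per_sample,
                          size = nb_dispersion, mu = mu),
                  nrow = n_genes)
      m <- rbind(m, rnbinom(n_cells_per_sample, size = nb_dispersion,
                            mu = kras_mu))
      all_counts[[sample_id]] <- m
      cd[[sample_id]] <- data.frame(sample_id = sample_id, class = cl,
                                    celltype = ct,
                                    stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(cbind, all_counts)
  rownames(mat) <- c(gene_ids, "KRAS")
  meta <- do.call(rbind, cd)
  colnames(mat) <- sprintf("%s_c%04d", meta$sample_id,
                           unlist(lapply(cd, function(d) seq_len(nrow(d)))))
  rownames(meta) <- colnames(mat)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(mat, sparse = TRUE)),
    colData = S4Vectors::DataFrame(meta))
  S4Vectors::metadata(sce)$truth <- list(program_genes = program_genes,
                                         composition_shift = shift,
                                         base_proportions = p0,
                                         marker_gene = "KRAS")
  sce
}

#' Render a synthetic three-channel fluorescence field with transcript spots
#'
#' Places non-overlapping nuclei on a jittered grid, draws a cytoplasmic
#' membrane-marker annulus for marker-positive cells, and plants
#' diffraction-limited transcript spots (hard discs of requested area,
#' optionally blurred by a Gaussian point-spread of `psf_sigma_px`) inside the
#' cytoplasm of marker-positive cells. Gaussian background noise is added and
#' clipped to [0, 1]. Entirely synthetic; intensities are arbitrary units.
#'
#' @param n_cells number of cells in the field.
#' @param marker_pos_fraction Bernoulli probability a cell is marker-positive.
#' @param spots_per_pos_cell either a non-negative integer (fixed count) or
#'   `list(type = "poisson", lambda = ...)`.
#' @param pixel_size_um physical pixel size (default 0.2 um/px, so the
#'   0.2-2 um^2 spot window maps to 5-50 px).
#' @param noise_sd Gaussian background SD (intensity units).
#' @param seed integer seed.
#' @param img_size field edge in px; NULL = smallest square grid that fits.
#' @param nucleus_radius_um,cyto_radius_um nucleus radius and cytoplasm
#'   expansion, um.
#' @param spot_area_um2 planted spot area, um^2.
#' @param psf_sigma_px Gaussian PSF sigma in px (0 disables blurring).
#' @return list with `image` (h x w x 3 array: nuclei, marker, spots),
#'   `truth` (`$cells` centroids + marker flags + planted spot counts;
#'   `$spots` coordinates/areas/owner), and `pixel_size_um`.
#' @export
gen_spot_image <- function(n_cells = 100, marker_pos_fraction = 0.5,
                           spots_per_pos_cell = list(type = "poisson", lambda = 2),
                           pixel_size_um = 0.2, noise_sd = 0.02, seed = 1L,
                           img_size = NULL, nucleus_radius_um = 3,
                           cyto_radius_um = 3, spot_area_um2 = 0.5,
                           psf_sigma_px = 0.5) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  set.seed(as.integer(seed))
  r_n <- round(nucleus_radius_um / pixel_size_um)
  r_c <- round(cyto_radius_um / pixel_size_um)
  spacing <- 2 * (r_n + r_c) + 6
  if (is.null(img_size)) {
    k <- ceiling(sqrt(n_cells))
    img_size <- k * spacing + spacing
  }
  k <- floor((img_size - spacing / 2) / spacing)
  if (k * k < n_cells)
    stop("field too small: ", img_size, "px fits at most ", k * k,
         " cells of this size, ", n_cells, " requested")

  h <- img_size; w <- img_size
  nuc <- matrix(0, h, w); mem <- matrix(0, h, w); spt <- matrix(0, h, w)

  slots <- expand.grid(gx = seq_len(k), gy = seq_len(k))
  slots <- slots[sample(nrow(slots), n_cells), , drop = FALSE]
  cx <- round(slots$gx * spacing - spacing / 2 + runif(n_cells, -2, 2))
  cy <- round(slots$gy * spacing - spacing / 2 + runif(n_cells, -2, 2))
  pos <- runif(n_cells) < marker_pos_fraction

  n_spots <- function(m) {
    if (is.numeric(spots_per_pos_cell)) return(rep(spots_per_pos_cell, m))
    if (identical(spots_per_pos_cell$type, "poisson"))
      return(rpois(m, spots_per_pos_cell$lambda))
    stop("unknown spots_per_pos_cell spec")
  }
  spot_counts <- ifelse(pos, n_spots(n_cells), 0L)

  disc_offsets <- function(r) {
    d <- ceiling(r)
    o <- expand.grid(dx = -d:d, dy = -d:d)
    o[o$dx^2 + o$dy^2 <= r^2, , drop = FALSE]
  }
  nuc_off <- disc_offsets(r_n)
  spot_r <- sqrt((spot_area_um2 / pixel_size_um^2) / pi)

  paint <- function(img, x, y, off, value) {
    px <- pmin(pmax(x + off$dx, 1), w)
    py <- pmin(pmax(y + off$dy, 1), h)
    img[cbind(py, px)] <- value
    img
  }

  spots <- list()
  for (i in seq_len(n_cells)) {
    nuc <- paint(nuc, cx[i], cy[i], nuc_off, 0.8)
    if (pos[i]) {
      ring <- disc_offsets(r_n + r_c)
      ring <- ring[ring$dx^2 + ring$dy^2 > r_n^2, , drop = FALSE]
      mem <- paint(mem, cx[i], cy[i], ring, 0.7)
    }
    if (spot_counts[i] > 0) {
      for (s in seq_len(spot_counts[i])) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, r_n + ceiling(spot_r) + 1, r_n + r_c - ceiling(spot_r) - 1)
        sx <- round(cx[i] + rad * cos(ang)); sy <- round(cy[i] + rad * sin(ang))
        spt <- paint(spt, sx, sy, disc_offsets(spot_r), 0.9)
        spots[[length(spots) + 1]] <-
          data.frame(x = sx, y = sy, area_um2 = spot_area_um2, cell_id = i)
      }
    }
  }
  if (psf_sigma_px > 0)
    spt <- as.matrix(EBImage::gblur(EBImage::Image(spt), sigma = psf_sigma_px))

  img <- array(0, dim = c(h, w, 3), dimnames = list(NULL, NULL,
               c("nuclei", "marker", "spots")))
  for (ch in 1:3) {
    base <- list(nuc, mem, spt)[[ch]]
    img[, , ch] <- pmin(pmax(base + rnorm(h * w, 0, noise_sd), 0), 1)
  }
  truth_cells <- data.frame(cell_id = seq_len(n_cells), x = cx, y = cy,
                            marker_pos = pos, n_spots = spot_counts)
  truth_spots <- if (length(spots)) do.call(rbind, spots) else
    data.frame(x = numeric(), y = numeric(), area_um2 = numeric(),
               cell_id = integer())
  list(image = img, truth = list(cells = truth_cells, spots = truth_spots),
       pixel_size_um = pixel_size_um)
}

#' Simulate a cyst-fluid biomarker cohort stratified by dysplasia grade
#'
#' Draws log-normal TNF-alpha concentrations per dysplasia grade with the
#' requested grade medians (log-normal median equals `exp(meanlog)`, so sample
#' medians converge to the targets). Invasive-cancer patients receive a tumor
#' T-stage label with a fixed share of minimally invasive (T1a) cases.
#'
#' @param n_per_grade patients per grade (LGD, HGD, IC).
#' @param medians_pg_ml target concentration medians, pg/mL.
#' @param log_sd common log-scale SD of concentrations.
#' @param t1a_fraction share of IC patients labeled T1a (count rounded).
#' @param seed integer seed.
#' @return data.frame(patient_id, grade, t_stage, tnfa_pg_ml); `t_stage` is NA
#'   outside IC.
#' @export
gen_cyst_cohort <- function(n_per_grade = c(27, 25, 28),
                            medians_pg_ml = c(3.21, 6.35, 11.65),
                            log_sd = 0.9, t1a_fraction = 8 / 28, seed = 1L) {
  if (length(n_per_grade) != 3 || any(n_per_grade < 0))
    stop("n_per_grade must be 3 non-negative counts")
  if (any(medians_pg_ml <= 0)) stop("medians must be positive")
  if (log_sd < 0) stop("log_sd must be >= 0")
  set.seed(as.integer(seed))
  grades <- c("LGD", "HGD", "IC")
  grade <- rep(grades, times = n_per_grade)
  conc <- unlist(lapply(1:3, function(i)
    rlnorm(n_per_grade[i], meanlog = log(medians_pg_ml[i]), sdlog = log_sd)))
  t_stage <- rep(NA_character_, length(grade))
  ic <- which(grade == "IC")
  if (length(ic)) {
    n_t1a <- round(t1a_fraction * length(ic))
    stage <- sample(c("T1b", "T2", "T3"), length(ic), replace = TRUE)
    stage[sample(length(ic), n_t1a)] <- "T1a"
    t_stage[ic] <- stage
  }
  data.frame(patient_id = sprintf("P%03d", seq_along(grade)),
             grade = factor(grade, levels = grades),
             t_stage = t_stage, tnfa_pg_ml = conc,
             stringsAsFactors = FALSE)
}
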