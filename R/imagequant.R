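# Rule-based in-situ spot quantification on multi-channel fluorescence
# fields. Images are plain numeric matrices in [0, 1], indexed [y, x];
# EBImage supplies the morphological machinery (median filter, Otsu,
# connected components, distance-transform watershed, seeded propagation).

.as_ebimage <- function(m) EBImage::Image(m)

#' Median-filter background subtraction
#'
#' Subtracts a `median_radius_px` median-filtered copy of the image from the
#' image itself and clips at zero, removing slowly varying background while
#' preserving diffraction-limited spots.
#'
#' @param img 2-D numeric matrix, values in [0, 1].
#' @param median_radius_px median filter radius (default 30 px).
#' @return background-subtracted matrix, min >= 0.
#' @export
subtract_background <- function(img, median_radius_px = 30) {
  if (length(dim(img)) != 2) stop("img must be a single-channel 2-D image")
  if (2 * median_radius_px + 1 > min(dim(img)))
    stop("median radius ", median_radius_px,
         " too large for a ", paste(dim(img), collapse = "x"), " image")
  bg <- EBImage::imageData(EBImage::medianFilter(.as_ebimage(img), median_radius_px))
  pmax(img - bg, 0)
}

# 1-D Otsu threshold (between-class variance maximization) over a numeric
# vector; used for per-cell mean intensities where image-based Otsu does not
# apply.
.otsu_1d <- function(x, n_breaks = 256) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_breaks)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_breaks)
  p <- h / sum(h)
  omega <- cumsum(p); mu <- cumsum(p * br)
  mu_t <- mu[n_breaks]
  sigma2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- 0
  # the split with class 1 = bins 1..k lies at the upper edge of bin k
  br[min(which.max(sigma2) + 1, n_breaks)]
}

#' Detect nuclei by thresholding, area filtering and watershed splitting
#'
#' Thresholds the nuclear channel (Otsu by default), labels connected
#' components, removes components below `min_area_um2`, and splits touching
#' nuclei by a distance-transform watershed.
#'
#' @param nuclear 2-D numeric matrix, values in [0, 1].
#' @param pixel_size_um physical pixel size.
#' @param threshold intensity threshold; NULL = Otsu on the channel.
#' @param min_area_um2 minimum nucleus area, um^2.
#' @param tolerance watershed merging tolerance (distance-map units).
#' @return a `kdn_cell_masks` list with `nucleus` (labeled integer matrix;
#'   all-zero when no foreground, with a message), `pixel_size_um`.
#' @export
detect_cells <- function(nuclear, pixel_size_um, threshold = NULL,
                         min_area_um2 = 5, tolerance = 1) {
  if (pixel_size_um <= 0) stop("pixel size must be known and positive")
  if (is.null(threshold))
    threshold <- EBImage::otsu(.as_ebimage(nuclear), range = c(0, 1))
  binary <- nuclear > threshold
  if (!any(binary)) {
    message("no foreground above threshold; returning empty mask")
    lab <- matrix(0L, nrow(nuclear), ncol(nuclear))
  } else {
    dm <- EBImage::distmap(.as_ebimage(binary))
    lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance))
    areas <- tabulate(lab[lab > 0])
    min_px <- min_area_um2 / pixel_size_um^2
    drop <- which(areas < min_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    # relabel sequentially
    kept <- sort(unique(lab[lab > 0]))
    lab[] <- match(lab, kept, nomatch = 0L)
  }
  structure(list(nucleus = lab, cell = lab, cytoplasm = 0L * lab,
                 pixel_size_um = pixel_size_um),
            class = "kdn_cell_masks")
}

#' Expand nuclei into cytoplasmic cell masks
#'
#' Dilates every nucleus by `round(radius_um / pixel_size_um)` pixels;
#' contested pixels between neighboring cells are resolved by seeded
#' propagation from the nuclei (nearest-nucleus assignment), so no pixel is
#' assigned to two cells.
#'
#' @param masks a `kdn_cell_masks` from [detect_cells()].
#' @param radius_um cytoplasm expansion radius (default 3 um).
#' @param pixel_size_um overrides the pixel size stored in `masks`.
#' @return the `kdn_cell_masks` with `cell` (nucleus + cytoplasm labels) and
#'   `cytoplasm` (ring-only labels) filled in.
#' @export
expand_cytoplasm <- function(masks, radius_um = 3, pixel_size_um = NULL) {
  psz <- if (is.null(pixel_size_um)) masks$pixel_size_um else pixel_size_um
  if (psz <= 0) stop("pixel size must be positive")
  r <- round(radius_um / psz)
  nuc <- masks$nucleus
  if (r == 0 || !any(nuc > 0)) {
    masks$cell <- nuc
    masks$cytoplasm <- 0L * nuc
    return(masks)
  }
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  dilated <- EBImage::imageData(EBImage::dilate(.as_ebimage(nuc > 0), brush)) > 0
  cell <- EBImage::imageData(EBImage::propagate(
    .as_ebimage(0 * nuc), seeds = .as_ebimage(nuc),
    mask = .as_ebimage(dilated)))
  storage.mode(cell) <- "integer"
  masks$cell <- cell
  masks$cytoplasm <- cell * (nuc == 0L)
  masks$pixel_size_um <- psz
  masks
}

#' Flag marker-positive cells by mean cytoplasmic marker intensity
#'
#' A cell is marker-positive when the mean marker intensity over its
#' cytoplasm ring exceeds the threshold (Otsu over the per-cell means when
#' not given). Cells with an empty ring fall back to the nucleus mask, with a
#' warning.
#'
#' @param masks a `kdn_cell_masks` with cytoplasm rings.
#' @param marker 2-D marker-channel matrix.
#' @param threshold intensity threshold; NULL = 1-D Otsu over per-cell means.
#' @return data.frame(cell_id, mean_marker, marker_pos).
#' @export
classify_marker_positive <- function(masks, marker, threshold = NULL) {
  ids <- sort(unique(masks$cell[masks$cell > 0]))
  if (!length(ids))
    return(data.frame(cell_id = integer(), mean_marker = numeric(),
                      marker_pos = logical()))
  ring_mean <- function(id) {
    px <- masks$cytoplasm == id
    if (!any(px)) return(NA_real_)
    mean(marker[px])
  }
  means <- vapply(ids, ring_mean, numeric(1))
  empty <- is.na(means)
  if (any(empty)) {
    warning(sum(empty), " cell(s) with empty cytoplasm ring; ",
            "marker measured over the nucleus mask instead")
    means[empty] <- vapply(ids[empty], function(id)
      mean(marker[masks$nucleus == id]), numeric(1))
  }
  if (is.null(threshold)) threshold <- .otsu_1d(means)
  data.frame(cell_id = ids, mean_marker = means,
             marker_pos = means > threshold)
}

#' Detect transcript spots with an intensity threshold and area window
#'
#' Thresholds the (background-subtracted) spot channel, labels connected
#' components, and keeps components whose physical area lies inside the
#' closed interval `area_window_um2` — boundary areas are kept.
#'
#' @param spot_channel 2-D numeric matrix.
#' @param pixel_size_um physical pixel size.
#' @param threshold intensity threshold; NULL = Otsu on the channel.
#' @param area_window_um2 inclusive (min, max) spot area, um^2
#'   (default c(0.2, 2)).
#' @return data.frame(spot_id, x, y, area_um2); empty for a blank image.
#' @export
detect_spots <- function(spot_channel, pixel_size_um, threshold = NULL,
                         area_window_um2 = c(0.2, 2)) {
  if (pixel_size_um <= 0) stop("pixel size must be known and positive")
  if (is.null(threshold))
    threshold <- EBImage::otsu(.as_ebimage(spot_channel), range = c(0, 1))
  binary <- spot_channel > threshold
  empty <- data.frame(spot_id = integer(), x = numeric(), y = numeric(),
                      area_um2 = numeric())
  if (!any(binary)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(.as_ebimage(binary)))
  idx <- which(lab > 0)
  labs <- lab[idx]
  ys <- ((idx - 1) %% nrow(lab)) + 1
  xs <- ((idx - 1) %/% nrow(lab)) + 1
  area_px <- tabulate(labs)
  area_um2 <- area_px * pixel_size_um^2
  cx <- tapply(xs, labs, mean); cy <- tapply(ys, labs, mean)
  keep <- which(area_um2 >= area_window_um2[1] &
                area_um2 <= area_window_um2[2])
  if (!length(keep)) return(empty)
  data.frame(spot_id = seq_along(keep), x = as.numeric(cx[as.character(keep)]),
             y = as.numeric(cy[as.character(keep)]),
             area_um2 = area_um2[keep])
}

#' Count spots per cell and summarize over marker-positive cells
#'
#' Assigns each detected spot to the cell whose mask contains its centroid
#' (spots outside every mask are tallied as unassigned) and summarizes the
#' per-cell counts over marker-positive cells only: the percentage of
#' positive cells with at least one spot, and the full spot-count
#' distribution in percent (sums to 100).
#'
#' @param spots data.frame from [detect_spots()].
#' @param masks a `kdn_cell_masks` with cell masks.
#' @param marker_flags data.frame from [classify_marker_positive()].
#' @return a `kdn_spot_quant` list: `per_cell` (cell_id, centroid, nucleus
#'   area, marker flag, spot count), `pct_positive_ge1`, `distribution_pct`
#'   (named by spot count), `n_unassigned_spots`.
#' @export
spots_per_cell <- function(spots, masks, marker_flags) {
  ids <- marker_flags$cell_id
  lab <- masks$cell
  owner <- if (nrow(spots)) {
    lab[cbind(pmin(pmax(round(spots$y), 1), nrow(lab)),
              pmin(pmax(round(spots$x), 1), ncol(lab)))]
  } else integer(0)
  n_unassigned <- sum(owner == 0)
  counts <- tabulate(owner[owner > 0], nbins = max(ids, 0))
  nuc_area <- tabulate(masks$nucleus[masks$nucleus > 0], nbins = max(ids, 0))
  cent <- function(id, which_dim) {
    px <- which(masks$nucleus == id)
    if (which_dim == "y") mean(((px - 1) %% nrow(lab)) + 1)
    else mean(((px - 1) %/% nrow(lab)) + 1)
  }
  per_cell <- data.frame(
    cell_id = ids,
    x = vapply(ids, cent, numeric(1), which_dim = "x"),
    y = vapply(ids, cent, numeric(1), which_dim = "y"),
    nucleus_area_um2 = nuc_area[ids] * masks$pixel_size_um^2,
    marker_pos = marker_flags$marker_pos,
    n_spots = counts[ids])
  pos <- per_cell[per_cell$marker_pos, ]
  if (nrow(pos)) {
    pct_ge1 <- 100 * mean(pos$n_spots >= 1)
    dist_tab <- table(pos$n_spots)
    dist_pct <- 100 * as.numeric(dist_tab) / nrow(pos)
    names(dist_pct) <- names(dist_tab)
  } else {
    pct_ge1 <- NA_real_; dist_pct <- numeric(0)
  }
  structure(list(per_cell = per_cell, pct_positive_ge1 = pct_ge1,
                 distribution_pct = dist_pct,
                 n_unassigned_spots = n_unassigned),
            class = "kdn_spot_quant")
}

#' @export
print.kdn_spot_quant <- function(x, ...) {
  cat("spot quantification over", nrow(x$per_cell), "cells (",
      sum(x$per_cell$marker_pos), "marker-positive )\n")
  cat(sprintf("%%positive cells with >= 1 spot: %.1f\n", x$pct_positive_ge1))
  cat(x$n_unassigned_spots, "spot(s) outside every cell mask\n")
  invisible(x)
}

#' Run the full spot-per-cell pipeline on a three-channel field
#'
#' Convenience wrapper: background-subtract the spot channel, detect nuclei,
#' expand cytoplasm, flag marker-positive cells, detect spots in the area
#' window, and count spots per marker-positive cell.
#'
#' @param img h x w x 3 array (nuclei, marker, spots) as produced by
#'   [gen_spot_image()], or any image with that channel order.
#' @param pixel_size_um physical pixel size.
#' @param median_radius_px background median-filter radius.
#' @param spot_threshold intensity threshold for spot calling (default 0.3,
#'   one third of a saturated spot; NULL = Otsu).
#' @param marker_threshold marker-positivity threshold (NULL = Otsu over
#'   per-cell means).
#' @param cyto_radius_um cytoplasm expansion.
#' @param area_window_um2 inclusive spot-area window.
#' @return a `kdn_spot_quant` (see [spots_per_cell()]).
#' @export
quantify_spot_image <- function(img, pixel_size_um, median_radius_px = 30,
                                spot_threshold = 0.3, marker_threshold = NULL,
                                cyto_radius_um = 3,
                                area_window_um2 = c(0.2, 2)) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  spot_bg <- subtract_background(img[, , 3], median_radius_px)
  masks <- detect_cells(img[, , 1], pixel_size_um)
  masks <- expand_cytoplasm(masks, cyto_radius_um)
  flags <- classify_marker_positive(masks, img[, , 2], marker_threshold)
  spots <- detect_spots(spot_bg, pixel_size_um, spot_threshold,
                        area_window_um2)
  spots_per_cell(spots, masks, flags)
}
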