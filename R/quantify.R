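#' Intensity statistics
#'
#' Per-disc summary statistics: phase-normalized marker means, ROI-based
#' intensity ratios (pouch/hinge, in/out of the zone of nonproliferating
#' cells, patch/adjacent), mask area fractions (EdU/DAPI), plain mean
#' intensities and polygon areas. All statistics are computed per disc;
#' cross-disc aggregation is a plain mean.
#'
#' @name quantify
NULL

#' Phase-normalized mean marker intensity
#'
#' The raw per-phase value is the mean marker intensity over the pixels of
#' that phase. Normalization mode `"mean_of_phases"` divides each raw mean
#' by the average of the per-phase means (the four normalized values then
#' average to 1); `"sum_of_phases"` divides by their sum (values sum to 1,
#' the relative contribution of each phase). Phases with no pixels are
#' reported as `NA` and excluded from the normalizer.
#'
#' @param marker 2-D numeric matrix.
#' @param labels a `phase_label_map` of the same shape.
#' @param mode normalization mode.
#' @return object of class `phase_profile_estimate`: a data frame with one
#'   row per phase (`phase`, `n_pixels`, `raw_mean`, `normalized`) and a
#'   `mode` attribute.
#' @export
phase_normalized_means <- function(marker, labels,
                                   mode = c("mean_of_phases", "sum_of_phases")) {
  assert_image(marker, "marker")
  mode <- match.arg(mode)
  if (!identical(dim(marker), dim(labels))) stop("marker and labels shapes differ")
  n_pixels <- tabulate(labels[labels > 0L], nbins = 4L)
  if (all(n_pixels == 0L)) stop("no phases present in label map")
  raw <- vapply(1:4, function(code) {
    if (n_pixels[code] == 0L) NA_real_ else mean(marker[labels == code])
  }, numeric(1))
  denom <- switch(mode,
                  mean_of_phases = mean(raw, na.rm = TRUE),
                  sum_of_phases = sum(raw, na.rm = TRUE))
  out <- data.frame(phase = PHASES, n_pixels = n_pixels,
                    raw_mean = raw, normalized = raw / denom)
  structure(out, mode = mode, class = c("phase_profile_estimate", "data.frame"))
}

#' Square/rectangular ROI sets
#'
#' An ROI set is a data frame with columns `name`, `role` (one of pouch,
#' hinge, in_domain, out_domain, patch, adjacent), `x`, `y` (pixel
#' coordinates of the top-left corner), `width_um`, `height_um`, plus a
#' `pixel_size` attribute (micrometres per pixel).
#'
#' @param rois data frame as described.
#' @param pixel_size micrometres per pixel.
#' @param image_shape optional `c(nrow, ncol)` bound check.
#' @return validated `roi_set`.
#' @export
roi_set <- function(rois, pixel_size, image_shape = NULL) {
  needed <- c("name", "role", "x", "y", "width_um", "height_um")
  if (!all(needed %in% names(rois)))
    stop("ROI table needs columns: ", paste(needed, collapse = ", "))
  roles <- c("pouch", "hinge", "in_domain", "out_domain", "patch", "adjacent")
  if (!all(rois$role %in% roles))
    stop("unknown ROI role; allowed: ", paste(roles, collapse = ", "))
  w_px <- round(rois$width_um / pixel_size)
  h_px <- round(rois$height_um / pixel_size)
  if (!is.null(image_shape)) {
    if (any(rois$y < 1) || any(rois$x < 1) ||
        any(rois$y + h_px - 1 > image_shape[1L]) ||
        any(rois$x + w_px - 1 > image_shape[2L]))
      stop("ROI extends beyond image bounds")
  }
  structure(rois, pixel_size = pixel_size, class = c("roi_set", "data.frame"))
}

roi_mean <- function(image, roi, pixel_size) {
  h <- round(roi$height_um / pixel_size)
  w <- round(roi$width_um / pixel_size)
  mean(image[roi$y:(roi$y + h - 1L), roi$x:(roi$x + w - 1L)])
}

#' ROI intensity ratio
#'
#' (mean over numerator-ROI means) / (mean over denominator-ROI means),
#' e.g., pouch-to-hinge, in/out of the ZNC, or patch-to-adjacent.
#'
#' @param image 2-D numeric matrix.
#' @param numerator_rois,denominator_rois `roi_set` objects (or data frames
#'   accepted by [roi_set()]; the `pixel_size` attribute must be present).
#' @return a single ratio.
#' @export
roi_ratio <- function(image, numerator_rois, denominator_rois) {
  assert_image(image)
  ps_n <- attr(numerator_rois, "pixel_size")
  ps_d <- attr(denominator_rois, "pixel_size")
  if (is.null(ps_n) || is.null(ps_d)) stop("ROI sets need a pixel_size attribute")
  if (nrow(numerator_rois) < 1L || nrow(denominator_rois) < 1L)
    stop("need at least one ROI on each side")
  num <- mean(vapply(seq_len(nrow(numerator_rois)),
                     function(i) roi_mean(image, numerator_rois[i, ], ps_n), numeric(1)))
  den <- mean(vapply(seq_len(nrow(denominator_rois)),
                     function(i) roi_mean(image, denominator_rois[i, ], ps_d), numeric(1)))
  if (den <= 0) stop("denominator ROI mean must be > 0")
  num / den
}

#' Fraction of mask A within the union (or intersection) of A and B
#'
#' The EdU/DAPI statistic: the area of A-positive pixels divided by the
#' area of the combined A/B support, optionally restricted to a region.
#' The default denominator is the union of the two masks, which bounds the
#' statistic in `[0, 1]`; an intersection denominator is available.
#'
#' @param mask_a,mask_b logical matrices.
#' @param region optional logical matrix restricting the computation.
#' @param denominator `"union"` (default) or `"intersection"`.
#' @return fraction in `[0, 1]` (union mode).
#' @export
area_fraction <- function(mask_a, mask_b, region = NULL,
                          denominator = c("union", "intersection")) {
  denominator <- match.arg(denominator)
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask shapes differ")
  if (is.null(region)) region <- matrix(TRUE, nrow(mask_a), ncol(mask_a))
  if (!identical(dim(mask_a), dim(region))) stop("region shape differs")
  den_mask <- if (denominator == "union") mask_a | mask_b else mask_a & mask_b
  den <- sum(den_mask & region)
  if (den == 0L) stop("empty denominator support")
  sum(mask_a & mask_b & region) / den
}

#' Mean intensity over a mask or ROI
#'
#' @param image 2-D numeric matrix.
#' @param support logical matrix, or a single-row `roi_set`.
#' @return arithmetic mean intensity.
#' @export
mean_intensity <- function(image, support) {
  assert_image(image)
  if (inherits(support, "roi_set") || (is.data.frame(support) && "width_um" %in% names(support))) {
    ps <- attr(support, "pixel_size")
    if (nrow(support) != 1L) stop("supply a single ROI")
    return(roi_mean(image, support[1L, ], ps))
  }
  if (!identical(dim(image), dim(support))) stop("support shape differs")
  if (sum(support) == 0L) stop("empty support")
  mean(image[support])
}

#' Area of a polygon region in square micrometres
#'
#' Rasterized pixel count times the squared pixel size.
#'
#' @param polygon a ring or list of rings in pixel coordinates.
#' @param pixel_size micrometres per pixel.
#' @param image_shape `c(nrow, ncol)` raster extent.
#' @return area in um^2.
#' @export
region_area <- function(polygon, pixel_size, image_shape) {
  mask <- rasterize_polygon(polygon, image_shape)
  n <- sum(mask)
  if (n == 0L) stop("degenerate polygon: no pixels covered")
  n * pixel_size^2
}

#' Estimate the additive background of a channel
#'
#' The median intensity over non-nuclear pixels, a robust estimate of the
#' constant imaging offset. Subtracting it before ROI ratio measurement
#' removes the dilution of compartment ratios toward 1 that a constant
#' offset causes.
#'
#' @param image 2-D numeric matrix.
#' @param nuclear_mask logical matrix; background is sampled where `FALSE`.
#' @return scalar background estimate.
#' @export
estimate_background <- function(image, nuclear_mask) {
  assert_image(image)
  if (!identical(dim(image), dim(nuclear_mask))) stop("mask shape differs")
  bgpx <- image[!nuclear_mask]
  if (length(bgpx) == 0L) stop("mask covers the whole image")
  stats::median(bgpx)
}

#' DAPI normalization of an intensity ratio
#'
#' Divides a marker pouch/hinge (or in/out) ratio by the matching DAPI
#' ratio, attributing shared density effects to nuclear content.
#'
#' @param ratio_marker,ratio_dapi numeric ratios; `ratio_dapi > 0`.
#' @return corrected ratio.
#' @export
dapi_normalize <- function(ratio_marker, ratio_dapi) {
  if (!is.numeric(ratio_dapi) || any(ratio_dapi <= 0))
    stop("ratio_dapi must be > 0")
  ratio_marker / ratio_dapi
}

#' Place non-overlapping square ROIs inside a region (test fixture helper)
#'
#' Seeded pseudo-random placement of `n` axis-aligned square ROIs fully
#' contained in the region mask, a stand-in for the manual placement of the
#' original analysis. A boundary margin (default 8 px, about one nucleus
#' diameter) keeps ROIs away from compartment edges, emulating the careful
#' interior placement of the manual procedure and avoiding the
#' nucleus-depleted rim at region borders.
#'
#' @param region_mask logical matrix.
#' @param role ROI role string.
#' @param n number of ROIs.
#' @param size_um ROI edge length in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed.
#' @param margin_px boundary margin in pixels.
#' @param max_tries placement attempts before giving up.
#' @return an `roi_set`.
#' @export
place_rois <- function(region_mask, role, n = 3, size_um = 15,
                       pixel_size = 0.5, seed = 1, margin_px = 8,
                       max_tries = 5000) {
  if (margin_px > 0)
    region_mask <- EBImage::erode(
      region_mask, EBImage::makeBrush(2L * as.integer(margin_px) + 1L, "disc")) > 0
  side <- as.integer(round(size_um / pixel_size))
  # integral image: a square fits iff every pixel under it is in the region
  ii <- apply(apply(region_mask, 2L, cumsum), 1L, cumsum)  # transposed cumsum
  ii <- t(ii)
  box_sum <- function(y, x) {
    y2 <- y + side - 1L; x2 <- x + side - 1L
    ii[y2, x2] -
      (if (y > 1L) ii[y - 1L, x2] else 0) -
      (if (x > 1L) ii[y2, x - 1L] else 0) +
      (if (y > 1L && x > 1L) ii[y - 1L, x - 1L] else 0)
  }
  set.seed(seed)
  placed <- data.frame()
  tries <- 0L
  while (nrow(placed) < n && tries < max_tries) {
    tries <- tries + 1L
    y <- sample.int(nrow(region_mask) - side + 1L, 1L)
    x <- sample.int(ncol(region_mask) - side + 1L, 1L)
    if (box_sum(y, x) < side * side) next
    if (nrow(placed) > 0L &&
        any(abs(placed$x - x) < side & abs(placed$y - y) < side)) next
    placed <- rbind(placed, data.frame(
      name = paste0(role, "_", nrow(placed) + 1L), role = role,
      x = x, y = y, width_um = size_um, height_um = size_um))
  }
  if (nrow(placed) < n) stop("could not place ", n, " ROIs in region")
  roi_set(placed, pixel_size, dim(region_mask))
}
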