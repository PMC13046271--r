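#' Mask-construction workflows
#'
#' These functions reproduce the Fiji-style mask chains used throughout the
#' imaging analysis: rolling-ball background subtraction, contrast-limited
#' adaptive histogram equalization (CLAHE), automatic Otsu / Moments (Tsai)
#' thresholding, and the preset nuclear and EdU mask workflows. Images are
#' plain numeric matrices in native arbitrary units; binary masks are logical
#' matrices carrying a `provenance` attribute naming the workflow that
#' produced them.
#'
#' @name segmentation
NULL

assert_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(arg, " must be a 2-D numeric matrix")
  invisible(image)
}

new_binary_mask <- function(mask, provenance) {
  structure(mask, provenance = provenance)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale morphological opening of
#' the image with a flat disc structuring element of the given radius and
#' subtracts it, clipping at zero. A flat background of any constant level
#' maps to (approximately) zero; features smaller than the structuring
#' radius are preserved.
#'
#' @param image 2-D numeric matrix.
#' @param radius structuring radius in pixels (default 100).
#' @return background-subtracted image, non-negative.
#' @export
rolling_ball_subtract <- function(image, radius = 100) {
  assert_image(image)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stop("radius must be a single number >= 1")
  side <- 2L * as.integer(floor(radius)) + 1L
  rng <- range(image)
  if (rng[2L] == rng[1L])  # flat: background is the image itself
    return(matrix(0, nrow(image), ncol(image)))
  # EBImage grayscale morphology operates on unit-range data
  x01 <- (image - rng[1L]) / (rng[2L] - rng[1L])
  bg <- EBImage::opening(x01, EBImage::makeBrush(side, shape = "disc"))
  background <- bg * (rng[2L] - rng[1L]) + rng[1L]
  pmax(image - background, 0)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tiled histogram equalization with a slope (clip) limit, parameterized as
#' in the Fiji plugin: a square block edge length in pixels, a histogram bin
#' count, and a maximum slope. The tile grid is derived from the block size
#' (`round(dim / block_size)` tiles per axis, at least one); the image is
#' edge-padded so its dimensions are exact tile multiples and cropped back
#' afterwards. Intensities are equalized on a `[min, max]`-scaled copy and
#' mapped back to the input range, so the output shares the input's
#' intensity convention. A constant image is returned unchanged.
#'
#' @param image 2-D numeric matrix.
#' @param block_size tile edge length in pixels, odd, >= 3 (default 127).
#' @param n_bins number of histogram bins, >= 2 (default 256).
#' @param max_slope contrast (clip) limit, >= 1 (default 3).
#' @return contrast-enhanced image in the input intensity range.
#' @export
clahe <- function(image, block_size = 127, n_bins = 256, max_slope = 3) {
  assert_image(image)
  if (block_size < 3 || block_size %% 2 != 1) stop("block_size must be odd and >= 3")
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (max_slope < 1) stop("max_slope must be >= 1")
  rng <- range(image)
  if (rng[2L] == rng[1L]) return(image)

  nx <- max(1L, as.integer(round(nrow(image) / block_size)))
  ny <- max(1L, as.integer(round(ncol(image) / block_size)))
  # pad with edge replication so dims are tile multiples (EBImage requirement)
  pad_to <- function(n, k) as.integer(ceiling(n / k) * k)
  nr <- pad_to(nrow(image), 2L * nx)
  nc <- pad_to(ncol(image), 2L * ny)
  x01 <- (image - rng[1L]) / (rng[2L] - rng[1L])
  padded <- x01[pmin(seq_len(nr), nrow(image)), pmin(seq_len(nc), ncol(image)), drop = FALSE]
  out <- EBImage::clahe(padded, nx = nx, ny = ny, bins = n_bins,
                        limit = max_slope, keep.range = TRUE)
  out <- out[seq_len(nrow(image)), seq_len(ncol(image)), drop = FALSE]
  out * (rng[2L] - rng[1L]) + rng[1L]
}

#' Otsu threshold of a histogram
#'
#' Returns the 0-based bin index `k` maximizing the between-class variance
#' when bins `0..k` form the background class. Ties resolve to the smallest
#' index.
#'
#' @param counts non-negative histogram counts.
#' @return integer bin index in `0..(length(counts) - 2)`.
#' @export
otsu_from_hist <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("histogram counts must be non-negative")
  n <- length(counts)
  p <- counts / sum(counts)
  i <- seq_len(n) - 1
  w0 <- cumsum(p)
  mu <- cumsum(p * i)
  mu_t <- mu[n]
  k <- seq_len(n - 1L)                       # candidate splits 0..n-2
  w0k <- w0[k]; w1k <- 1 - w0k
  bcv <- ifelse(w0k > 0 & w1k > 0, (mu_t * w0k - mu[k])^2 / (w0k * w1k), -Inf)
  as.integer(which.max(bcv) - 1L)
}

#' Moments (Tsai) threshold of a histogram
#'
#' Moment-preserving thresholding: the threshold is chosen so that the
#' first three gray-level moments of the binarized image match those of the
#' original histogram; the bin index returned is the first whose cumulative
#' frequency exceeds the background fraction of Tsai's closed-form solution.
#'
#' @param counts non-negative histogram counts.
#' @return integer bin index (0-based).
#' @export
moments_from_hist <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("histogram counts must be non-negative")
  p <- counts / sum(counts)
  i <- seq_along(p) - 1
  m1 <- sum(i * p); m2 <- sum(i^2 * p); m3 <- sum(i^3 * p)
  cd <- m2 - m1^2
  if (cd <= 0) stop("degenerate histogram: moments threshold undefined")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) disc <- 0
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  pd <- (z1 - m1) / (z1 - z0)                 # background fraction
  cum <- cumsum(p)
  idx <- which(cum > pd)
  if (length(idx) == 0L) idx <- length(p)
  as.integer(idx[1L] - 1L)
}

image_histogram <- function(image, n_bins = 256) {
  rng <- range(image)
  width <- (rng[2L] - rng[1L]) / n_bins
  bin <- pmin(as.integer(floor((image - rng[1L]) / width)), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  list(counts = counts, min = rng[1L], width = width)
}

#' Automatic intensity threshold (Otsu or Moments)
#'
#' Histograms use 256 bins spanning the observed intensity range, matching
#' 8-bit tool behavior while accepting floating-point input. The returned
#' threshold is the upper edge of the selected bin, so the foreground is
#' `image > threshold` under the dark-background convention.
#'
#' @param image 2-D numeric matrix with at least two distinct values.
#' @param method `"otsu"` or `"moments"`.
#' @param n_bins histogram bins (default 256).
#' @return a single threshold intensity inside the observed range.
#' @export
auto_threshold <- function(image, method = c("otsu", "moments"), n_bins = 256) {
  assert_image(image)
  method <- match.arg(method)
  rng <- range(image)
  if (rng[1L] == rng[2L])
    stop("constant image: threshold undefined")
  h <- image_histogram(image, n_bins)
  k <- switch(method,
              otsu = otsu_from_hist(h$counts),
              moments = moments_from_hist(h$counts))
  h$min + (k + 1) * h$width
}

# Sequential pairwise averaging, as done channel by channel with the Fiji
# Image Calculator: avg(avg(c1, c2), c3), ...
average_sequentially <- function(channels) {
  out <- channels[[1L]]
  for (ch in channels[-1L]) out <- (out + ch) / 2
  out
}

#' Nuclear mask presets
#'
#' Three preset chains mirroring the workflow variants used for EdU
#' quantification, phase-distribution scoring and phase-resolved marker
#' quantification:
#' \describe{
#'   \item{`dapi_moments`}{rolling-ball subtraction (r = 100) -> CLAHE
#'     (block 127, 256 bins, slope 3) -> Moments threshold on the DAPI
#'     channel.}
#'   \item{`dapi_otsu`}{same chain with an Otsu threshold.}
#'   \item{`averaged_otsu`}{sequential averaging of all supplied nuclear
#'     channels followed by an Otsu threshold (no background subtraction or
#'     CLAHE).}
#' }
#'
#' @param channels list of 2-D numeric matrices; the first is the DAPI
#'   channel for the `dapi_*` workflows.
#' @param workflow preset name.
#' @param radius rolling-ball radius in pixels.
#' @param clahe_block,clahe_bins,clahe_slope CLAHE parameters.
#' @return logical mask with a `provenance` attribute.
#' @export
make_nuclear_mask <- function(channels,
                              workflow = c("dapi_moments", "dapi_otsu", "averaged_otsu"),
                              radius = 100, clahe_block = 127,
                              clahe_bins = 256, clahe_slope = 3) {
  if (is.matrix(channels)) channels <- list(channels)
  if (length(channels) < 1L) stop("at least one channel required")
  workflow <- match.arg(workflow)
  lapply(channels, assert_image)
  if (workflow == "averaged_otsu") {
    avg <- average_sequentially(channels)
    thr <- auto_threshold(avg, "otsu")
    return(new_binary_mask(avg > thr, "averaged_otsu"))
  }
  img <- rolling_ball_subtract(channels[[1L]], radius)
  img <- clahe(img, clahe_block, clahe_bins, clahe_slope)
  method <- if (workflow == "dapi_moments") "moments" else "otsu"
  thr <- auto_threshold(img, method)
  new_binary_mask(img > thr, workflow)
}

#' EdU mask
#'
#' Gaussian blur (sigma = 2 px) followed by a Moments threshold under the
#' dark-background convention. `sigma = 0` skips the blur.
#'
#' @param edu_image 2-D numeric matrix.
#' @param sigma blur standard deviation in pixels.
#' @return logical mask with provenance `"edu_moments"`.
#' @export
make_edu_mask <- function(edu_image, sigma = 2) {
  assert_image(edu_image, "edu_image")
  img <- if (sigma > 0) EBImage::gblur(edu_image, sigma = sigma) else edu_image
  thr <- auto_threshold(img, "moments")
  new_binary_mask(img > thr, "edu_moments")
}

#' Pixelwise conjunction of masks
#'
#' The binary "AND" used to restrict masks to a manually drawn region. The
#' second operand may be a polygon, which is rasterized (even-odd rule,
#' pixel centers) to the first operand's shape.
#'
#' @param a logical mask.
#' @param b logical mask of the same shape, or a polygon.
#' @return logical mask.
#' @export
intersect_masks <- function(a, b) {
  if (!is.matrix(a) || !is.logical(a)) stop("a must be a logical matrix")
  if (!is.matrix(b)) b <- rasterize_polygon(b, dim(a))
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  new_binary_mask(a & b, paste0(attr(a, "provenance") %||% "mask", "+and"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
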