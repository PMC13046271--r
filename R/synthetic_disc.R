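#' Synthetic wing-disc image generator
#'
#' Generates multi-channel images of a wing-disc epithelium with known
#' ground truth, so that segmentation, FUCCI classification and intensity
#' quantification can be validated without microscopy data. Nuclei are hard
#' discs placed on a jittered hexagonal lattice restricted to the pouch and
#' hinge polygons -- emulating the dense, near-crystalline packing of the
#' disc epithelium -- with per-nucleus cell-cycle phase, FUCCI reporter
#' intensities following the four-phase scheme, and marker channels driven
#' by per-phase profiles and a pouch multiplier, under additive Gaussian
#' noise clipped at zero.
#'
#' @name synthetic_disc
NULL

#' Per-phase marker intensity profile
#'
#' Relative intensity multipliers (unitless, strictly positive) applied to
#' a marker's base intensity in each cell-cycle phase.
#'
#' @param g1,early_s,late_s,g2 multipliers.
#' @return named numeric vector of class `phase_profile`.
#' @export
phase_profile <- function(g1 = 1, early_s = 1, late_s = 1, g2 = 1) {
  p <- c(g1 = g1, early_s = early_s, late_s = late_s, g2 = g2)
  if (any(!is.finite(p)) || any(p <= 0)) stop("phase multipliers must be > 0")
  structure(p, class = "phase_profile")
}

#' FUCCI reporter intensity scheme
#'
#' Mean GFP and RFP intensities (arbitrary units) per phase, encoding the
#' reporter logic: G1 GFP-high/RFP-low, early S both low, late S
#' GFP-low/RFP-high, G2 both high. The default separates an "off" level
#' (reporter fully degraded, 5 a.u.) from the residual early-S level
#' (15 a.u.) and the expressed level (100 a.u.), so that thresholds derived
#' from early-S nuclei sit above the off level with margin at realistic
#' noise while still separating all phases exactly at zero noise.
#'
#' @param gfp,rfp named numeric vectors with entries g1, early_s, late_s, g2.
#' @return object of class `fucci_scheme`.
#' @export
fucci_scheme <- function(gfp = c(g1 = 100, early_s = 15, late_s = 5, g2 = 100),
                         rfp = c(g1 = 5, early_s = 15, late_s = 100, g2 = 100)) {
  ph <- c("g1", "early_s", "late_s", "g2")
  gfp <- gfp[ph]; rfp <- rfp[ph]
  if (any(!is.finite(c(gfp, rfp))) || any(c(gfp, rfp) < 0))
    stop("reporter intensities must be finite and >= 0")
  if (!(min(gfp[c("g1", "g2")]) > max(gfp[c("early_s", "late_s")])))
    stop("scheme violates reporter logic: GFP must be high in G1 and G2 only")
  if (!(min(rfp[c("late_s", "g2")]) > max(rfp[c("g1", "early_s")])))
    stop("scheme violates reporter logic: RFP must be high in late S and G2 only")
  structure(list(gfp = gfp, rfp = rfp), class = "fucci_scheme")
}

#' Marker channel specification
#'
#' @param profile a [phase_profile()].
#' @param base_intensity base intensity in a.u.
#' @param pouch_multiplier multiplier applied inside the pouch (> 0).
#' @return list of class `marker_spec`.
#' @export
marker_spec <- function(profile = phase_profile(), base_intensity = 100,
                        pouch_multiplier = 1) {
  if (pouch_multiplier <= 0) stop("pouch_multiplier must be > 0")
  if (base_intensity <= 0) stop("base_intensity must be > 0")
  structure(list(profile = phase_profile(profile[["g1"]], profile[["early_s"]],
                                         profile[["late_s"]], profile[["g2"]]),
                 base_intensity = base_intensity,
                 pouch_multiplier = pouch_multiplier),
            class = "marker_spec")
}

#' Default pouch polygon (regular 32-gon)
#' @param image_shape `c(nrow, ncol)`.
#' @param radius_frac radius as a fraction of the smaller image dimension.
#' @return data frame with columns x, y.
#' @export
default_pouch_polygon <- function(image_shape = c(384, 384), radius_frac = 0.26) {
  r <- radius_frac * min(image_shape)
  cx <- image_shape[2L] / 2; cy <- image_shape[1L] / 2
  th <- seq(0, 2 * pi, length.out = 33L)[-33L]
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Default hinge polygon (annulus as outer + inner ring)
#' @param image_shape `c(nrow, ncol)`.
#' @param inner_frac,outer_frac annulus radii as fractions of the smaller
#'   image dimension.
#' @return list of two rings (even-odd annulus).
#' @export
default_hinge_polygon <- function(image_shape = c(384, 384),
                                  inner_frac = 0.30, outer_frac = 0.443) {
  cx <- image_shape[2L] / 2; cy <- image_shape[1L] / 2
  th <- seq(0, 2 * pi, length.out = 33L)[-33L]
  ring <- function(r) data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
  list(outer = ring(outer_frac * min(image_shape)),
       inner = ring(inner_frac * min(image_shape)))
}

#' Specification of a synthetic disc
#'
#' Defaults describe a 192 x 192 um field (384 px at 0.5 um/px) with 500
#' nuclei of radius 2 +/- 0.2 um, a central pouch and a surrounding hinge
#' annulus, phase proportions (0.3, 0.2, 0.2, 0.3), the default FUCCI
#' scheme, one H3K27ac-like marker, additive Gaussian noise of 5 a.u. and
#' a background of 2 a.u.
#'
#' @param image_shape `c(nrow, ncol)` in pixels.
#' @param pixel_size micrometres per pixel.
#' @param n_nuclei number of nuclei.
#' @param nucleus_radius `c(mean, sd)` in micrometres (truncated at 2.5 sd).
#' @param pouch_polygon,hinge_polygon region polygons (pixel coordinates);
#'   must be non-self-intersecting and mutually disjoint.
#' @param phase_proportions 4-vector on the simplex (G1, early S, late S, G2).
#' @param fucci a [fucci_scheme()].
#' @param markers named list of [marker_spec()] objects.
#' @param dapi_intensity per-nucleus DAPI level (constant by default).
#' @param dapi_s_ramp if `TRUE`, DAPI scales with DNA content (1x in G1
#'   ramping to 2x in G2, intermediate in S).
#' @param noise_sd additive Gaussian noise standard deviation (a.u.).
#' @param background_level constant background (a.u.).
#' @param phase_sampling `"exact"` (largest-remainder allocation, shuffled)
#'   or `"multinomial"` (i.i.d. sampling).
#' @param seed integer seed; identical seeds give bit-identical discs.
#' @return validated list of class `disc_spec`.
#' @export
disc_spec <- function(image_shape = c(384, 384), pixel_size = 0.5,
                      n_nuclei = 500, nucleus_radius = c(2.0, 0.2),
                      pouch_polygon = default_pouch_polygon(image_shape),
                      hinge_polygon = default_hinge_polygon(image_shape),
                      phase_proportions = c(0.3, 0.2, 0.2, 0.3),
                      fucci = fucci_scheme(),
                      markers = list(H3K27ac = marker_spec()),
                      dapi_intensity = 100, dapi_s_ramp = FALSE,
                      noise_sd = 5, background_level = 2,
                      phase_sampling = c("exact", "multinomial"),
                      seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 32))
  if (abs(sum(phase_proportions) - 1) > 1e-9)
    stop("phase_proportions must sum to 1")
  if (any(phase_proportions < 0)) stop("phase_proportions must be >= 0")
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  if (noise_sd < 0 || background_level < 0)
    stop("noise_sd and background_level must be >= 0")
  if (!inherits(fucci, "fucci_scheme")) stop("fucci must be a fucci_scheme")
  if (length(markers) > 0 &&
      (is.null(names(markers)) || any(names(markers) == "")))
    stop("markers must be a named list")
  validate_polygon(pouch_polygon, "pouch_polygon")
  validate_polygon(hinge_polygon, "hinge_polygon")
  pm <- rasterize_polygon(pouch_polygon, image_shape)
  hm <- rasterize_polygon(hinge_polygon, image_shape)
  if (any(pm & hm)) stop("pouch and hinge polygons must be disjoint")
  structure(list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_nuclei = as.integer(n_nuclei), nucleus_radius = nucleus_radius,
    pouch_polygon = pouch_polygon, hinge_polygon = hinge_polygon,
    phase_proportions = phase_proportions, fucci = fucci, markers = markers,
    dapi_intensity = dapi_intensity, dapi_s_ramp = dapi_s_ramp,
    noise_sd = noise_sd, background_level = background_level,
    phase_sampling = match.arg(phase_sampling), seed = as.integer(seed)),
    class = "disc_spec")
}

# Hexagonal lattice sites whose centers fall inside the region mask,
# ordered along a serpentine path (row by row, alternating direction).
hex_sites <- function(region_mask, pitch) {
  dy <- pitch * sqrt(3) / 2
  rows <- seq(1, nrow(region_mask), by = dy)
  sites <- NULL
  for (k in seq_along(rows)) {
    offset <- if (k %% 2L == 0L) pitch / 2 else 0
    xs <- seq(1 + offset, ncol(region_mask), by = pitch)
    if (k %% 2L == 0L) xs <- rev(xs)
    y <- rows[k]
    keep <- region_mask[cbind(pmin(round(y), nrow(region_mask)),
                              pmin(round(xs), ncol(region_mask)))]
    if (any(keep)) sites <- rbind(sites, cbind(x = xs[keep], y = y))
  }
  sites
}

# Largest-remainder allocation of n items to proportions p.
allocate_counts <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

phase_key <- c("g1", "early_s", "late_s", "g2")

#' Generate a synthetic disc
#'
#' Places nuclei without overlap inside the pouch/hinge union, assigns each
#' a phase, and renders every channel as
#' `background + nucleus contribution + Gaussian noise` (clipped at zero),
#' where the nucleus contribution is the FUCCI scheme value for GFP/RFP,
#' `base_intensity x profile[phase] x pouch_multiplier` (if the nucleus
#' center lies in the pouch) for marker channels, and a constant (optionally
#' DNA-content-ramped) level for DAPI.
#'
#' @param spec a [disc_spec()].
#' @return object of class `synthetic_disc`: a list with `channels` (named
#'   list of matrices: DAPI, GFP, RFP, one per marker), `truth_labels`
#'   (integer label image), `nuclei` (data frame: id, x, y, radius_px,
#'   phase, region), `region_masks` (pouch, hinge) and the `spec`.
#' @export
generate_disc <- function(spec) {
  if (!inherits(spec, "disc_spec")) stop("spec must be a disc_spec")
  set.seed(spec$seed)
  shape <- spec$image_shape
  ps <- spec$pixel_size
  pouch_mask <- rasterize_polygon(spec$pouch_polygon, shape)
  hinge_mask <- rasterize_polygon(spec$hinge_polygon, shape)
  region_mask <- pouch_mask | hinge_mask

  r_mean <- spec$nucleus_radius[1L] / ps
  r_sd <- spec$nucleus_radius[2L] / ps
  r_max <- r_mean + 2.5 * r_sd
  jitter_amp <- 0.75
  pitch <- 2 * r_max + 1 + 2 * jitter_amp
  sites <- hex_sites(region_mask, pitch)
  n_sites <- if (is.null(sites)) 0L else nrow(sites)
  if (spec$n_nuclei > n_sites)
    stop("geometry too dense: cannot place ", spec$n_nuclei,
         " non-overlapping nuclei (", n_sites, " sites available)")

  # systematic thinning along the serpentine path keeps density uniform
  if (spec$n_nuclei < n_sites) {
    step <- n_sites / spec$n_nuclei
    start <- stats::runif(1L, 0, step)
    idx <- unique(pmin(n_sites, 1L + floor(start + step * (seq_len(spec$n_nuclei) - 1L))))
    while (length(idx) < spec$n_nuclei)  # collisions from rounding
      idx <- unique(c(idx, sample.int(n_sites, spec$n_nuclei - length(idx))))
    sites <- sites[sort(idx), , drop = FALSE]
  }
  n <- spec$n_nuclei
  cx <- sites[, "x"] + stats::runif(n, -jitter_amp, jitter_amp)
  cy <- sites[, "y"] + stats::runif(n, -jitter_amp, jitter_amp)
  radii <- pmin(pmax(stats::rnorm(n, r_mean, r_sd),
                     r_mean - 2.5 * r_sd), r_max)
  radii <- pmax(radii, 0.5)

  phases <- switch(spec$phase_sampling,
    exact = {
      pool <- rep.int(1:4, allocate_counts(n, spec$phase_proportions))
      pool[sample.int(length(pool))]
    },
    multinomial = sample.int(4L, n, replace = TRUE, prob = spec$phase_proportions))
  in_pouch <- pouch_mask[cbind(pmin(pmax(round(cy), 1L), shape[1L]),
                               pmin(pmax(round(cx), 1L), shape[2L]))]

  labels <- matrix(0L, shape[1L], shape[2L])
  for (k in seq_len(n)) {
    y0 <- max(1L, floor(cy[k] - radii[k])); y1 <- min(shape[1L], ceiling(cy[k] + radii[k]))
    x0 <- max(1L, floor(cx[k] - radii[k])); x1 <- min(shape[2L], ceiling(cx[k] + radii[k]))
    ys <- y0:y1; xs <- x0:x1
    d2 <- outer((ys - cy[k])^2, (xs - cx[k])^2, `+`)
    hit <- d2 <= radii[k]^2
    if (any(labels[ys, xs][hit] != 0L))
      stop("internal error: overlapping nuclei")  # excluded by construction
    block <- labels[ys, xs]; block[hit] <- k
    labels[ys, xs] <- block
  }

  dapi_scale <- if (spec$dapi_s_ramp) c(1, 4 / 3, 5 / 3, 2) else c(1, 1, 1, 1)
  per_nucleus <- list(
    DAPI = spec$dapi_intensity * dapi_scale[phases],
    GFP = as.numeric(spec$fucci$gfp[phase_key[phases]]),
    RFP = as.numeric(spec$fucci$rfp[phase_key[phases]]))
  for (mname in names(spec$markers)) {
    m <- spec$markers[[mname]]
    per_nucleus[[mname]] <- m$base_intensity *
      as.numeric(m$profile[phase_key[phases]]) *
      ifelse(in_pouch, m$pouch_multiplier, 1)
  }

  channels <- list()
  for (ch in names(per_nucleus)) {
    img <- matrix(spec$background_level, shape[1L], shape[2L])
    inside <- labels > 0L
    img[inside] <- img[inside] + per_nucleus[[ch]][labels[inside]]
    if (spec$noise_sd > 0)
      img <- pmax(img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                               shape[1L], shape[2L]), 0)
    channels[[ch]] <- img
  }

  nuclei <- data.frame(id = seq_len(n), x = cx, y = cy, radius_px = radii,
                       phase = PHASES[phases],
                       region = ifelse(in_pouch, "pouch", "hinge"))
  structure(list(channels = channels, truth_labels = labels, nuclei = nuclei,
                 region_masks = list(pouch = pouch_mask, hinge = hinge_mask),
                 spec = spec),
            class = "synthetic_disc")
}

#' @export
print.synthetic_disc <- function(x, ...) {
  cat(sprintf("synthetic disc: %d x %d px, %d nuclei, channels: %s\n",
              nrow(x$truth_labels), ncol(x$truth_labels), nrow(x$nuclei),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Ground-truth nuclear mask of a synthetic disc
#' @param disc a `synthetic_disc`.
#' @return logical matrix (`truth_labels > 0`).
#' @export
truth_mask <- function(disc) {
  new_binary_mask(disc$truth_labels > 0L, "truth")
}
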