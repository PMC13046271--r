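#' Pipeline configuration and end-to-end run
#'
#' A run configuration holds every stage parameter (defaulting to the
#' analysis parameters: rolling ball r = 100, CLAHE 127/256/3, 500-bp bins,
#' basemean cutoff 25, alpha = 0.1, 5 reference nuclei) plus the seed.
#' [run_pipeline()] chains simulate -> segment -> classify -> quantify and
#' the genomics track, writing tab-separated tables with a provenance
#' header and TIFF images/masks. Identical configurations produce
#' byte-identical table bodies.
#'
#' @name pipeline_io
NULL

default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    disc = list(
      image_shape = c(384L, 384L), pixel_size = 0.5, n_nuclei = 500L,
      nucleus_radius = c(2.0, 0.2), phase_proportions = c(0.3, 0.2, 0.2, 0.3),
      noise_sd = 5, background_level = 2,
      marker_name = "H3K27ac",
      marker_profile = c(1, 1, 1, 1), marker_base = 100,
      pouch_multiplier = 1
    ),
    segmentation = list(
      workflow = "dapi_otsu", radius = 100L,
      clahe_block = 127L, clahe_bins = 256L, clahe_slope = 3
    ),
    fucci = list(n_reference_nuclei = 5L),
    quantify = list(normalization = "mean_of_phases", n_rois = 3L,
                    roi_size_um = 15),
    counts = list(
      n_regions = c(shared = 500L, unique_wt = 250L, unique_kd = 250L,
                    no_peak_bin = 1000L),
      true_lfc = c(shared = 0, unique_wt = 0, unique_kd = 0, no_peak_bin = 0),
      baseline_mean = 200, dispersion = 0.05, n_replicates = 2L,
      basemean_min = 25, alpha = 0.1
    )
  )
}

check_known_keys <- function(cfg, template, path = "") {
  for (key in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(template))
      stop("unknown config key: ", full)
    if (is.list(template[[key]]) && !is.null(names(template[[key]])) &&
        is.list(cfg[[key]]))
      check_known_keys(cfg[[key]], template[[key]], full)
  }
}

modify_defaults <- function(defaults, overrides) {
  for (key in names(overrides)) {
    if (is.list(defaults[[key]]) && is.list(overrides[[key]]))
      defaults[[key]] <- modify_defaults(defaults[[key]], overrides[[key]])
    else defaults[[key]] <- overrides[[key]]
  }
  defaults
}

#' Build a validated run configuration
#'
#' @param config a YAML file path or a (possibly partial) nested list of
#'   overrides; unknown keys are rejected by name.
#' @return full configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- default_config()
  check_known_keys(config, defaults)
  structure(modify_defaults(defaults, config), class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(config, stage, msg) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, msg))
}

provenance_header <- function(config) {
  c(sprintf("# fuccidisc %s",
            as.character(utils::packageVersion("fuccidisc"))),
    sprintf("# config_hash: %s", config_hash(config)))
}

#' Write a table as TSV with a provenance header
#' @param x data frame.
#' @param path output file.
#' @param header character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(x, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed TSV
#' @param path file written by [write_tsv_prov()].
#' @return data frame.
#' @export
read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write image channels as a multi-page TIFF
#'
#' One 32-bit float page per channel, intensities divided by `scale` to fit
#' the unit range expected by the TIFF writer.
#'
#' @param channels named list of numeric matrices.
#' @param path output file.
#' @param scale intensity divisor (stored nowhere; pass the same value to
#'   [read_disc_tiff()]).
#' @return `path`, invisibly.
#' @export
write_disc_tiff <- function(channels, path, scale = 65536) {
  pages <- lapply(channels, function(ch) ch / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_disc_tiff()]
#' @param path file path.
#' @param scale intensity multiplier.
#' @return list of numeric matrices.
#' @export
read_disc_tiff <- function(path, scale = 65536) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) p * scale)
}

#' Write a binary mask or small-integer label map as 8-bit TIFF
#' @param mask logical or small-integer matrix (values 0..255).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (is.logical(mask)) m <- m * 255
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit TIFF mask or label map
#' @param path file path.
#' @param logical if `TRUE`, return a logical mask (> 0).
#' @return logical or integer matrix.
#' @export
read_mask_tiff <- function(path, logical = TRUE) {
  m <- round(tiff::readTIFF(path) * 255)
  if (logical) m > 0 else matrix(as.integer(m), nrow(m), ncol(m))
}

#' Run the full pipeline
#'
#' Imaging track: generate a synthetic disc, write its channels and ground
#' truth, build the nuclear mask with the configured preset, derive FUCCI
#' thresholds from the configured number of reference early-S nuclei
#' (ground-truth identities, as on annotated data), classify nuclear
#' pixels, and write phase fractions, the phase-normalized marker profile
#' and the pouch/hinge ROI ratio. Genomics track: simulate a categorized
#' count dataset, compute combined spike-in + H3 size factors, run the NB
#' differential test and write per-region results and category summaries.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param outdir output directory, created if missing.
#' @return invisibly, a list with the in-memory stage results and file paths.
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  config <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(config)
  paths <- list()
  dc <- config$disc

  pipeline_log(config, "simulate", "generating synthetic disc")
  mp <- dc$marker_profile
  markers <- stats::setNames(list(marker_spec(
    profile = phase_profile(mp[1], mp[2], mp[3], mp[4]),
    base_intensity = dc$marker_base,
    pouch_multiplier = dc$pouch_multiplier)), dc$marker_name)
  spec <- disc_spec(image_shape = dc$image_shape, pixel_size = dc$pixel_size,
                    n_nuclei = dc$n_nuclei, nucleus_radius = dc$nucleus_radius,
                    phase_proportions = dc$phase_proportions,
                    markers = markers, noise_sd = dc$noise_sd,
                    background_level = dc$background_level,
                    seed = config$seed)
  disc <- generate_disc(spec)
  paths$channels <- file.path(outdir, "disc_channels.tiff")
  write_disc_tiff(disc$channels, paths$channels)
  paths$truth <- file.path(outdir, "disc_truth.tsv")
  write_tsv_prov(disc$nuclei, paths$truth, hdr)
  paths$pouch_polygon <- file.path(outdir, "pouch_polygon.csv")
  utils::write.csv(spec$pouch_polygon, paths$pouch_polygon, row.names = FALSE)

  pipeline_log(config, "segment", paste("workflow", config$segmentation$workflow))
  sg <- config$segmentation
  nmask <- make_nuclear_mask(disc$channels["DAPI"], workflow = sg$workflow,
                             radius = sg$radius, clahe_block = sg$clahe_block,
                             clahe_bins = sg$clahe_bins,
                             clahe_slope = sg$clahe_slope)
  paths$nuclear_mask <- file.path(outdir, "nuclear_mask.tiff")
  write_mask_tiff(nmask, paths$nuclear_mask)

  pipeline_log(config, "classify", "deriving thresholds and classifying pixels")
  k <- config$fucci$n_reference_nuclei
  ref_ids <- disc$nuclei$id[disc$nuclei$phase == "EARLY_S"][seq_len(k)]
  thr <- derive_thresholds(disc$channels$GFP, disc$channels$RFP,
                           ref_ids, labels = disc$truth_labels)
  labels <- classify_pixels(disc$channels$GFP, disc$channels$RFP, thr, nmask)
  paths$labels <- file.path(outdir, "phase_labels.tiff")
  write_mask_tiff(unclass(labels), paths$labels)
  fr <- phase_fractions(labels)
  paths$fractions <- file.path(outdir, "phase_fractions.tsv")
  write_tsv_prov(data.frame(phase = names(fr), fraction = as.numeric(fr)),
                 paths$fractions, hdr)

  pipeline_log(config, "quantify", "phase profile and ROI ratio")
  marker_img <- disc$channels[[dc$marker_name]]
  profile <- phase_normalized_means(marker_img, labels,
                                    mode = config$quantify$normalization)
  paths$profile <- file.path(outdir, "phase_profile.tsv")
  write_tsv_prov(as.data.frame(profile), paths$profile, hdr)
  qc <- config$quantify
  pouch_rois <- place_rois(disc$region_masks$pouch, "pouch", qc$n_rois,
                           qc$roi_size_um, dc$pixel_size, seed = config$seed)
  hinge_rois <- place_rois(disc$region_masks$hinge, "hinge", qc$n_rois,
                           qc$roi_size_um, dc$pixel_size,
                           seed = config$seed + 1L)
  marker_bg <- estimate_background(marker_img, nmask)
  ratio <- roi_ratio(marker_img - marker_bg, pouch_rois, hinge_rois)
  paths$roi_ratio <- file.path(outdir, "roi_ratio.tsv")
  write_tsv_prov(data.frame(statistic = "pouch_hinge_ratio", value = ratio),
                 paths$roi_ratio, hdr)

  pipeline_log(config, "cuttag", "simulating counts and testing")
  cc <- config$counts
  csim <- generate_counts(count_sim_spec(
    n_regions = cc$n_regions, true_lfc = cc$true_lfc,
    baseline_mean = cc$baseline_mean, dispersion = cc$dispersion,
    n_replicates = cc$n_replicates, seed = config$seed))
  sf <- compute_size_factors(csim$sample_info$spikein_total, csim$h3_counts)
  res <- nb_differential(csim$counts, csim$sample_info, sf,
                         regions = csim$regions,
                         basemean_min = cc$basemean_min, alpha = cc$alpha)
  paths$differential <- file.path(outdir, "differential.tsv")
  write_tsv_prov(as.data.frame(res), paths$differential, hdr)
  summ <- summarize_categories(res)
  paths$summary <- file.path(outdir, "category_summary.tsv")
  write_tsv_prov(summ, paths$summary, hdr)

  invisible(list(disc = disc, nuclear_mask = nmask, thresholds = thr,
                 labels = labels, fractions = fr, profile = profile,
                 roi_ratio = ratio, counts = csim, size_factors = sf,
                 differential = res, summary = summ, paths = paths))
}
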