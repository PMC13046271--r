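#' Synthetic CUT&Tag count simulator
#'
#' Simulates negative-binomial fragment counts over categorized genomic
#' regions (peaks shared between conditions, unique to either, and 500-bp
#' bins with no called peak) with known true log2 fold changes, per-sample
#' sequencing depths implied by spike-in totals, and matched histone-H3
#' count profiles, so that normalization and differential testing can be
#' validated against ground truth.
#'
#' @name synthetic_counts
NULL

#' Specification of a count simulation
#'
#' @param n_regions named integer vector: regions per category
#'   (`shared`, `unique_wt`, `unique_kd`, `no_peak_bin`).
#' @param true_lfc named numeric vector: true log2 fold change (KD vs WT)
#'   per category.
#' @param baseline_mean expected normalized count of a region at depth 1.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2), >= 0;
#'   0 gives Poisson counts.
#' @param n_replicates replicates per condition (>= 2).
#' @param spikein_depths per-sample spike-in totals (length
#'   `2 * n_replicates`, WT then KD); default 1000 each.
#' @param h3_depths per-H3-sample relative depths; default 1 each.
#' @param n_h3_regions rows of the simulated H3 count matrix.
#' @param h3_mean mean H3 count per region at depth 1.
#' @param seed integer seed.
#' @return validated list of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_regions = c(shared = 500, unique_wt = 250,
                                         unique_kd = 250, no_peak_bin = 1000),
                           true_lfc = c(shared = 0, unique_wt = 0,
                                        unique_kd = 0, no_peak_bin = 0),
                           baseline_mean = 200, dispersion = 0.05,
                           n_replicates = 2, spikein_depths = NULL,
                           h3_depths = NULL, n_h3_regions = 500,
                           h3_mean = 200, seed = 1L) {
  cats <- c("shared", "unique_wt", "unique_kd", "no_peak_bin")
  if (!all(cats %in% names(n_regions))) stop("n_regions must name all categories")
  if (!all(cats %in% names(true_lfc))) stop("true_lfc must name all categories")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_replicates < 2) stop("need n_replicates >= 2")
  n_samples <- 2L * n_replicates
  if (is.null(spikein_depths)) spikein_depths <- rep(1000, n_samples)
  if (is.null(h3_depths)) h3_depths <- rep(1, n_samples)
  if (length(spikein_depths) != n_samples || length(h3_depths) != n_samples)
    stop("spikein_depths and h3_depths must have one entry per sample")
  if (any(spikein_depths <= 0) || any(h3_depths <= 0)) stop("depths must be > 0")
  structure(list(n_regions = n_regions[cats], true_lfc = true_lfc[cats],
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 n_replicates = as.integer(n_replicates),
                 spikein_depths = spikein_depths, h3_depths = h3_depths,
                 n_h3_regions = as.integer(n_h3_regions), h3_mean = h3_mean,
                 seed = as.integer(seed)),
            class = "count_sim_spec")
}

rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a categorized count dataset
#'
#' Per-region counts are NB draws with mean
#' `baseline_mean x depth_s x 2^(true_lfc)` in the knockdown condition
#' (`x 1` in WT), where `depth_s` is the sample's spike-in total relative
#' to the 1000-fragment reference, times its H3 relative depth. The H3
#' count matrix is a flat profile scaled by `h3_depths`. Identical seeds
#' give identical tables.
#'
#' @param spec a [count_sim_spec()].
#' @return list of class `count_sim`: `regions` (data frame with chrom,
#'   start, end, category, true_lfc), `counts` (region x sample matrix),
#'   `sample_info` (sample, condition, replicate, spikein_total,
#'   h3_sample), `h3_counts` (region x H3-sample matrix).
#' @export
generate_counts <- function(spec) {
  if (!inherits(spec, "count_sim_spec")) stop("spec must be a count_sim_spec")
  set.seed(spec$seed)
  n_rep <- spec$n_replicates
  cond <- rep(c("WT", "KD"), each = n_rep)
  repl <- rep(paste0("r", seq_len(n_rep)), times = 2L)
  samples <- paste(cond, repl, sep = "_")
  depth <- (spec$spikein_depths / 1000) * spec$h3_depths

  n_total <- sum(spec$n_regions)
  category <- rep(names(spec$n_regions), times = spec$n_regions)
  lfc <- rep(as.numeric(spec$true_lfc), times = spec$n_regions)
  # synthetic coordinates: peak categories get 1-kb intervals, no-peak
  # bins are exactly 500 bp, all laid end to end on one contig
  width <- ifelse(category == "no_peak_bin", 500L, 1000L)
  end <- cumsum(width)
  regions <- data.frame(chrom = "chrSim", start = end - width, end = end,
                        category = category, true_lfc = lfc)

  counts <- matrix(0L, n_total, length(samples),
                   dimnames = list(NULL, samples))
  for (s in seq_along(samples)) {
    mu <- spec$baseline_mean * depth[s] *
      (if (cond[s] == "KD") 2^lfc else rep(1, n_total))
    counts[, s] <- rnb(n_total, mu, spec$dispersion)
  }

  h3_samples <- paste0("H3_", samples)
  h3_counts <- matrix(0L, spec$n_h3_regions, length(samples),
                      dimnames = list(NULL, h3_samples))
  for (s in seq_along(samples)) {
    h3_counts[, s] <- stats::rpois(spec$n_h3_regions,
                                   spec$h3_mean * spec$h3_depths[s])
  }

  sample_info <- data.frame(sample = samples, condition = cond,
                            replicate = repl,
                            spikein_total = spec$spikein_depths,
                            h3_sample = h3_samples)
  structure(list(regions = regions, counts = counts,
                 sample_info = sample_info, h3_counts = h3_counts,
                 spec = spec),
            class = "count_sim")
}
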