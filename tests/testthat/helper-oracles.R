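# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately use naive scalar loops so they share no
# code path with the package implementation.

# Exhaustive between-class-variance Otsu over all candidate splits.
oracle_otsu <- function(counts) {
  p <- counts / sum(counts)
  n <- length(p)
  best <- -Inf; best_k <- 0L
  for (k in 0:(n - 2L)) {
    w0 <- sum(p[1:(k + 1L)]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum((0:k) * p[1:(k + 1L)]) / w0
    m1 <- sum(((k + 1L):(n - 1L)) * p[(k + 2L):n]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_k <- k }
  }
  best_k
}

# Tsai's moment-preserving threshold, scalar transliteration of the
# published closed form.
oracle_moments <- function(counts) {
  p <- counts / sum(counts)
  m1 <- 0; m2 <- 0; m3 <- 0
  for (i in seq_along(p)) {
    g <- i - 1
    m1 <- m1 + g * p[i]; m2 <- m2 + g^2 * p[i]; m3 <- m3 + g^3 * p[i]
  }
  cd <- m2 - m1 * m1
  c0 <- (-m2 * m2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  z0 <- 0.5 * (-c1 - sqrt(c1 * c1 - 4 * c0))
  z1 <- 0.5 * (-c1 + sqrt(c1 * c1 - 4 * c0))
  pd <- (z1 - m1) / (z1 - z0)
  s <- 0
  for (i in seq_along(p)) {
    s <- s + p[i]
    if (s > pd) return(i - 1L)
  }
  length(p) - 1L
}

# Per-pixel transliteration of the four-phase rule.
oracle_classify <- function(gfp, rfp, gt, rt, mask) {
  out <- matrix(0L, nrow(gfp), ncol(gfp))
  for (i in seq_len(nrow(gfp))) for (j in seq_len(ncol(gfp))) {
    if (!mask[i, j]) next
    g <- gfp[i, j]; r <- rfp[i, j]
    out[i, j] <-
      if (g > gt && r > rt) 4L else
      if (g > gt && r <= rt) 1L else
      if (g <= gt && r <= rt) 2L else 3L
  }
  out
}

# O(n^2) interval categorization: merge by sweep, then pairwise overlaps.
oracle_categorize <- function(wt, kd, bins, bin_size = 500) {
  ov <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  all_pk <- rbind(wt, kd)
  all_pk <- all_pk[order(all_pk$chrom, all_pk$start), ]
  merged <- NULL
  for (i in seq_len(nrow(all_pk))) {
    r <- all_pk[i, ]
    if (!is.null(merged) && merged$chrom[nrow(merged)] == r$chrom &&
        merged$end[nrow(merged)] >= r$start) {
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], r$end)
    } else merged <- rbind(merged, r[, c("chrom", "start", "end")])
  }
  cat_m <- character(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    hw <- any(wt$chrom == merged$chrom[i] &
                ov(wt$start, wt$end, merged$start[i], merged$end[i]))
    hk <- any(kd$chrom == merged$chrom[i] &
                ov(kd$start, kd$end, merged$start[i], merged$end[i]))
    cat_m[i] <- if (hw && hk) "shared" else if (hw) "unique_wt" else "unique_kd"
  }
  merged$category <- cat_m
  keep <- logical(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    hit <- any(merged$chrom == bins$chrom[i] &
                 ov(merged$start, merged$end, bins$start[i], bins$end[i]))
    keep[i] <- !hit && (bins$end[i] - bins$start[i]) == bin_size
  }
  nb <- bins[keep, , drop = FALSE]
  if (nrow(nb)) nb$category <- "no_peak_bin"
  out <- rbind(merged, nb)
  out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# Shoelace polygon area (continuous), for the rasterized-area comparison.
oracle_shoelace <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# A small fast disc spec for tests that do not need 500 nuclei.
small_disc_spec <- function(n_nuclei = 80, ...) {
  disc_spec(image_shape = c(192, 192), n_nuclei = n_nuclei, ...)
}

# Ground-truth S-phase pixel mask of a synthetic disc.
s_phase_mask <- function(disc) {
  s_ids <- disc$nuclei$id[disc$nuclei$phase %in% c("EARLY_S", "LATE_S")]
  matrix(disc$truth_labels %in% s_ids, nrow(disc$truth_labels))
}

# EdU marker: strong incorporation in S phase, trace elsewhere.
edu_marker <- function(contrast = 10, background = 10) {
  marker_spec(phase_profile(0.1, contrast, contrast, 0.1),
              base_intensity = background, pouch_multiplier = 1)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
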