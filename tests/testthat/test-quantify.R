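label_map <- function(m) structure(m, phases = PHASES, class = "phase_label_map")

test_that("phase-normalized means follow the two normalization conventions", {
  labs <- label_map(matrix(rep(1:4, each = 25), 10, 10))
  marker <- matrix(rep(c(2, 4, 6, 8), each = 25), 10, 10)
  est <- phase_normalized_means(marker, labs, "mean_of_phases")
  expect_equal(est$normalized, c(0.4, 0.8, 1.2, 1.6))
  expect_equal(mean(est$normalized), 1, tolerance = 1e-12)
  est_s <- phase_normalized_means(marker, labs, "sum_of_phases")
  expect_equal(est_s$normalized, c(2, 4, 6, 8) / 20)
  expect_equal(sum(est_s$normalized), 1, tolerance = 1e-12)
  flat <- phase_normalized_means(matrix(5, 10, 10), labs)
  expect_equal(flat$normalized, rep(1, 4))
  # a missing phase is NA and excluded from the normalizer
  labs3 <- label_map(matrix(rep(c(1L, 2L, 4L, 4L), each = 25), 10, 10))
  est3 <- phase_normalized_means(marker, labs3)
  expect_true(is.na(est3$normalized[3]))
  expect_equal(mean(est3$normalized, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_error(phase_normalized_means(marker, label_map(matrix(0L, 10, 10))),
               "no phases")
})

test_that("marker phase profiles are recovered from noisy synthetic discs", {
  prof <- phase_profile(0.85, 1.30, 1.25, 0.90)
  recov <- sapply(1:3, function(s) {
    d <- generate_disc(disc_spec(
      markers = list(M = marker_spec(prof, 100, 1)), noise_sd = 5, seed = 30 + s))
    ref <- d$nuclei$id[d$nuclei$phase == "EARLY_S"][1:5]
    thr <- derive_thresholds(d$channels$GFP, d$channels$RFP, ref,
                             labels = d$truth_labels)
    labs <- classify_pixels(d$channels$GFP, d$channels$RFP, thr, truth_mask(d))
    phase_normalized_means(d$channels$M, labs)$normalized
  })
  target <- as.numeric(prof) / mean(prof)
  expect_true(all(abs(rowMeans(recov) - target) < 0.05))
})

test_that("ROI ratios are ratios of mean ROI means and are scale invariant", {
  img <- matrix(0, 60, 60)
  img[1:10, 1:10] <- 10; img[1:10, 21:30] <- 10; img[1:10, 41:50] <- 10
  img[31:40, 1:10] <- 20; img[31:40, 21:30] <- 20; img[31:40, 41:50] <- 20
  ps <- 1
  pouch <- roi_set(data.frame(name = paste0("p", 1:3), role = "pouch",
                              x = c(1, 21, 41), y = 1, width_um = 10,
                              height_um = 10), ps)
  hinge <- roi_set(data.frame(name = paste0("h", 1:3), role = "hinge",
                              x = c(1, 21, 41), y = 31, width_um = 10,
                              height_um = 10), ps)
  expect_equal(roi_ratio(img, pouch, hinge), 0.5)
  expect_equal(roi_ratio(img, pouch, pouch), 1.0)
  expect_equal(roi_ratio(img * 37, pouch, hinge), 0.5)  # scale invariance
  expect_error(roi_ratio(matrix(0, 60, 60), pouch, hinge), "> 0")
})

test_that("pouch/hinge ratios recover the generator pouch multiplier", {
  ratios <- sapply(1:5, function(s) {
    d <- generate_disc(disc_spec(
      markers = list(M = marker_spec(phase_profile(), 100, 2.0)),
      noise_sd = 5, seed = 40 + s))
    bg <- estimate_background(d$channels$M, truth_mask(d))
    pr <- place_rois(d$region_masks$pouch, "pouch", 3, 15, 0.5, seed = s)
    hr <- place_rois(d$region_masks$hinge, "hinge", 3, 15, 0.5, seed = s + 60)
    roi_ratio(d$channels$M - bg, pr, hr)
  })
  expect_lt(abs(mean(ratios) / 2.0 - 1), 0.15)
})

test_that("area fractions follow set arithmetic", {
  a <- matrix(FALSE, 10, 10); a[1:5, ] <- TRUE
  expect_equal(area_fraction(a, a), 1.0)
  b <- matrix(FALSE, 10, 10); b[6:8, ] <- TRUE
  # disjoint masks under the union denominator
  expect_equal(area_fraction(a, b), 0)
  expect_equal(sum(a) / (sum(a) + sum(b)), 50 / 80)
  set.seed(41)
  for (rep in 1:5) {
    x <- matrix(runif(100) > 0.5, 10, 10)
    y <- matrix(runif(100) > 0.5, 10, 10)
    r <- matrix(runif(100) > 0.2, 10, 10)
    want <- sum(x & y & r) / sum((x | y) & r)
    expect_equal(area_fraction(x, y, r), want)
    want_i <- sum(x & y & r) / sum(x & y & r)
    expect_equal(area_fraction(x, y, r, "intersection"), want_i)
  }
  none <- matrix(FALSE, 10, 10)
  expect_error(area_fraction(none, none), "empty denominator")
})

test_that("EdU/DAPI area fraction matches the S-phase ground truth", {
  spec <- disc_spec(markers = list(EdU = edu_marker(10, 10)),
                    noise_sd = 0, background_level = 10, seed = 42)
  d <- generate_disc(spec)
  edu <- unclass(make_edu_mask(d$channels$EdU))[, ]
  dapi <- unclass(make_nuclear_mask(d$channels["DAPI"], "dapi_moments"))[, ]
  frac <- area_fraction(edu, dapi, d$region_masks$pouch)
  truth <- mean(d$nuclei$phase[d$nuclei$region == "pouch"] %in%
                  c("EARLY_S", "LATE_S"))
  expect_lt(abs(frac - truth), 0.1)
})

test_that("mean intensity equals the direct sum/area oracle", {
  img <- matrix(7, 12, 12)
  expect_equal(mean_intensity(img, matrix(TRUE, 12, 12)), 7)
  half <- matrix(c(0, 10), 12, 12)
  expect_equal(mean_intensity(half, matrix(TRUE, 12, 12)), 5)
  set.seed(43)
  im <- matrix(runif(144), 12, 12)
  m <- matrix(runif(144) > 0.6, 12, 12)
  expect_equal(mean_intensity(im, m), sum(im[m]) / sum(m))
  expect_error(mean_intensity(im, matrix(FALSE, 12, 12)), "empty support")
})

test_that("polygon areas match pixel arithmetic and the shoelace formula", {
  sq <- data.frame(x = c(0.5, 100.5, 100.5, 0.5), y = c(0.5, 0.5, 100.5, 100.5))
  expect_equal(region_area(sq, 0.5, c(120, 120)), 100 * 100 * 0.25)
  expect_error(region_area(data.frame(x = c(1, 1, 1), y = c(1, 1, 1)),
                           0.5, c(50, 50)), "degenerate")
  set.seed(44)
  for (rep in 1:5) {
    th <- sort(runif(12, 0, 2 * pi))
    r <- runif(12, 30, 55)
    ring <- data.frame(x = 60 + r * cos(th), y = 60 + r * sin(th))
    raster_um2 <- region_area(ring, 1, c(120, 120))
    expect_lt(abs(raster_um2 / oracle_shoelace(ring) - 1), 0.02)
  }
})

test_that("DAPI normalization divides out the density ratio", {
  expect_equal(dapi_normalize(1.5, 1.0), 1.5)
  expect_equal(dapi_normalize(1.5, 1.5), 1.0)
  expect_equal(dapi_normalize(2.0, 0.8), 2.5)
  expect_error(dapi_normalize(1, 0), "> 0")
})

test_that("ROI placement produces in-bounds, non-overlapping, in-region squares", {
  d <- generate_disc(disc_spec(seed = 45))
  rs <- place_rois(d$region_masks$pouch, "pouch", 3, 15, 0.5, seed = 9)
  expect_equal(nrow(rs), 3L)
  side <- 30L
  for (i in 1:3) {
    px <- d$region_masks$pouch[rs$y[i]:(rs$y[i] + side - 1L),
                               rs$x[i]:(rs$x[i] + side - 1L)]
    expect_true(all(px))
  }
  # deterministic given the seed
  expect_identical(rs, place_rois(d$region_masks$pouch, "pouch", 3, 15, 0.5,
                                  seed = 9))
})
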