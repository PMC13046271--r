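test_that("genome tiling covers every chromosome exactly", {
  b <- tile_genome(c(chr1 = 1250), 500)
  expect_equal(b$start, c(0, 500, 1000))
  expect_equal(b$end, c(500, 1000, 1250))
  one <- tile_genome(c(chrX = 500), 500)
  expect_equal(nrow(one), 1L)
  set.seed(51)
  sizes <- setNames(sample(200:5000, 5), paste0("chr", 1:5))
  tiles <- tile_genome(sizes, 500)
  covered <- tapply(tiles$end - tiles$start, tiles$chrom, sum)
  expect_equal(as.numeric(covered[names(sizes)]), unname(as.numeric(sizes)))
  expect_error(tile_genome(c(chr1 = 1000), 0), "bin_size")
})

test_that("region categorization handles the forced overlap cases", {
  bins <- tile_genome(c(chr1 = 2000), 500)
  rc <- categorize_regions(data.frame(chrom = "chr1", start = 100, end = 200),
                           data.frame(chrom = "chr1", start = 150, end = 250),
                           bins)
  pk <- rc[rc$category != "no_peak_bin", ]
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 100); expect_equal(pk$end, 250)
  expect_equal(pk$category, "shared")

  rc2 <- categorize_regions(data.frame(chrom = "chr1", start = 100, end = 200),
                            data.frame(chrom = "chr1", start = 300, end = 400),
                            bins)
  pk2 <- rc2[rc2$category != "no_peak_bin", ]
  expect_equal(pk2$category, c("unique_wt", "unique_kd"))
  # only bins with zero peak overlap remain, all exactly 500 bp
  np <- rc2[rc2$category == "no_peak_bin", ]
  expect_equal(np$start, c(500, 1000, 1500))
})

test_that("categorization equals the quadratic overlap oracle on random instances", {
  set.seed(52)
  bins <- tile_genome(c(c1 = 5000, c2 = 3200), 500)
  for (rep in 1:40) {
    mk <- function(n) {
      s <- sample(0:4500, n)
      data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                 start = s, end = s + sample(50:600, n, TRUE))
    }
    wt <- mk(sample(1:25, 1)); kd <- mk(sample(1:25, 1))
    got <- as.data.frame(categorize_regions(wt, kd, bins))
    got <- got[order(got$chrom, got$start), ]; rownames(got) <- NULL
    want <- oracle_categorize(wt, kd, bins)
    want <- want[order(want$chrom, want$start), ]; rownames(want) <- NULL
    expect_equal(got, want)
    expect_true(!any(duplicated(got[c("chrom", "start")])))
  }
})

test_that("size factors reproduce symmetric and geometric-mean examples", {
  h3_equal <- matrix(rep(c(50, 100, 200, 400), times = 4), ncol = 4)
  sf <- compute_size_factors(c(a = 1000, b = 1000, c = 1000, d = 1000),
                             h3_equal, center = "geomean")
  expect_equal(sf$combined, rep(1, 4))
  sf2 <- compute_size_factors(c(1000, 2000), h3_equal[, 1:2],
                              center = "geomean")
  expect_equal(sf2$spikein_factor, c(1 / sqrt(2), sqrt(2)))
  # default reference scaling gives the same answer up to one global constant
  sf3 <- compute_size_factors(c(1000, 2000), h3_equal[, 1:2])
  expect_equal(sf3$combined / sf2$combined,
               rep(sf3$combined[1] / sf2$combined[1], 2))
  expect_error(compute_size_factors(c(0, 1000), h3_equal[, 1:2]), "> 0")
})

test_that("combined factors recover simulated depth ratios", {
  depths <- c(800, 1500, 1200, 600)
  cs <- generate_counts(count_sim_spec(spikein_depths = depths, seed = 53))
  sf <- compute_size_factors(cs$sample_info$spikein_total, cs$h3_counts)
  expect_true(all(abs(sf$combined / (depths / 1000) - 1) < 0.02))
})

test_that("scaling a sample's depth leaves its normalized counts unchanged", {
  cs <- generate_counts(count_sim_spec(seed = 54))
  sf <- compute_size_factors(cs$sample_info$spikein_total, cs$h3_counts)
  base <- sweep(cs$counts, 2, sf$combined, `/`)
  for (c_scale in c(0.1, 10)) {
    counts2 <- cs$counts
    counts2[, 2] <- counts2[, 2] * c_scale
    totals2 <- cs$sample_info$spikein_total
    totals2[2] <- totals2[2] * c_scale
    sf2 <- compute_size_factors(totals2, cs$h3_counts)
    norm2 <- sweep(counts2, 2, sf2$combined, `/`)
    expect_lt(max(abs(norm2 / base - 1), na.rm = TRUE), 1e-9)
  }
})

test_that("median-of-ratios matches the DESeq-style reference factors", {
  set.seed(55)
  base <- rpois(300, 200) + 1
  m <- cbind(a = base, b = round(base * 2.0), c = round(base * 0.5))
  f <- median_of_ratios(m)
  expect_equal(unname(f / f[1]), c(1, 2, 0.5), tolerance = 0.02)
})

test_that("null and exact-ratio differential cases behave as forced", {
  info <- data.frame(sample = c("WT_r1", "WT_r2", "KD_r1", "KD_r2"),
                     condition = c("WT", "WT", "KD", "KD"),
                     replicate = c("r1", "r2", "r1", "r2"))
  sf <- rep(1, 4)
  same <- matrix(rep(c(100, 150, 200), each = 4), ncol = 4, byrow = TRUE)
  r <- nb_differential(same, info, sf)
  expect_equal(r$log2fc_raw, rep(0, 3), tolerance = 1e-8)
  expect_equal(r$p, rep(1, 3), tolerance = 1e-6)

  toy <- matrix(c(100, 100, 400, 400), nrow = 1)
  rt <- nb_differential(toy, info, sf)
  expect_equal(rt$log2fc_raw, 2, tolerance = 1e-8)

  expect_error(nb_differential(toy, transform(info, condition = "WT"), sf),
               "two conditions")
  expect_error(nb_differential(-toy, info, sf), "negative")
  # basemean filter discards low regions before testing
  low <- matrix(c(10, 12, 11, 9, 100, 100, 400, 400), nrow = 2, byrow = TRUE)
  rl <- nb_differential(low, info, sf)
  expect_false(rl$tested[1]); expect_true(is.na(rl$p[1]))
  expect_true(rl$tested[2])
})

test_that("shrunken fold changes never exceed raw ones in magnitude", {
  cs <- generate_counts(count_sim_spec(
    true_lfc = c(shared = 1, unique_wt = -1, unique_kd = 0.5, no_peak_bin = 0),
    n_regions = c(shared = 100, unique_wt = 100, unique_kd = 100,
                  no_peak_bin = 200), seed = 56))
  sf <- compute_size_factors(cs$sample_info$spikein_total, cs$h3_counts)
  r <- nb_differential(cs$counts, cs$sample_info, sf, regions = cs$regions)
  ok <- !is.na(r$log2fc_shrunk)
  expect_true(all(abs(r$log2fc_shrunk[ok]) <= abs(r$log2fc_raw[ok]) + 1e-12))
  expect_true(all(r$padj >= r$p - 1e-12, na.rm = TRUE))
  expect_true(all(r$pass_filter == (r$tested & !is.na(r$padj) & r$padj < 0.1)))
})

test_that("category summaries count significant directions correctly", {
  res <- structure(data.frame(
    category = rep(c("shared", "no_peak_bin"), each = 4),
    log2fc_raw = c(1, 2, -1, 1, 0.1, -0.1, 0.2, -0.2),
    log2fc_shrunk = c(0.9, 1.8, -0.9, 0.9, 0.05, -0.05, 0.1, -0.1),
    padj = c(0.01, 0.05, 0.2, 0.01, 0.5, 0.6, 0.7, 0.8),
    tested = TRUE),
    class = c("differential_result", "data.frame"), alpha = 0.1)
  s <- summarize_categories(res)
  sh <- s[s$category == "shared", ]
  expect_equal(sh$n_tested, 4); expect_equal(sh$pct_up, 75)
  expect_equal(sh$pct_down, 0)
  np <- s[s$category == "no_peak_bin", ]
  expect_equal(np$pct_up + np$pct_down, 0)
  expect_true(all(s$pct_up + s$pct_down <= 100))
})

test_that("power to detect unit fold changes stays at its calibrated level", {
  cs <- generate_counts(count_sim_spec(
    true_lfc = c(shared = 1, unique_wt = 0, unique_kd = 0, no_peak_bin = 0),
    n_regions = c(shared = 300, unique_wt = 100, unique_kd = 100,
                  no_peak_bin = 500), seed = 57))
  sf <- compute_size_factors(cs$sample_info$spikein_total, cs$h3_counts)
  r <- nb_differential(cs$counts, cs$sample_info, sf, regions = cs$regions)
  sh <- r$category == "shared"
  expect_gte(mean(r$padj[sh] < 0.1, na.rm = TRUE), 0.6)
})

test_that("differential direction agrees with an independent DESeq2 fit", {
  skip_if_not_installed("DESeq2")
  cs <- generate_counts(count_sim_spec(
    true_lfc = c(shared = 1.5, unique_wt = -1.5, unique_kd = 0, no_peak_bin = 0),
    n_regions = c(shared = 80, unique_wt = 80, unique_kd = 40,
                  no_peak_bin = 100), seed = 58))
  sf <- compute_size_factors(cs$sample_info$spikein_total, cs$h3_counts)
  mine <- nb_differential(cs$counts, cs$sample_info, sf, regions = cs$regions)

  coldata <- data.frame(condition = factor(cs$sample_info$condition,
                                           levels = c("WT", "KD")),
                        replicate = factor(cs$sample_info$replicate))
  dds <- DESeq2::DESeqDataSetFromMatrix(cs$counts, coldata,
                                        ~ replicate + condition)
  DESeq2::sizeFactors(dds) <- sf$combined
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  expect_gt(cor(mine$log2fc_raw, res$log2FoldChange, use = "complete.obs"), 0.95)
  both_sig <- which(mine$padj < 0.1 & res$padj < 0.1)
  expect_true(all(sign(mine$log2fc_raw[both_sig]) ==
                    sign(res$log2FoldChange[both_sig])))
})
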