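# fuccidisc

Quantitative analysis of cell cycle–linked histone-modification dynamics
in the *Drosophila* wing imaginal disc, re-implemented as a tested R
package. It is aimed at imaging and epigenomics analysts who want the
full computational chain — from raw multi-channel disc images (or
synthetic stand-ins with known ground truth) to per-phase marker
statistics, and from CUT&Tag region counts to per-category differential
calls — as reproducible, scriptable functions rather than an interactive
ImageJ/GraphPad workflow.

## What it computes

**Imaging track.** Nuclei in the wing pouch are classified into
cell-cycle phases using the FUCCI reporter pair (a degradable GFP-E2F1
fragment and an RFP-CycB fragment). With a per-disc threshold pair
*(t_G, t_R)* derived from the average reporter intensity of five early-S
nuclei, every nuclear pixel is labeled

| GFP | RFP | phase |
|-----|-----|-------|
| > t_G | > t_R | G2 |
| > t_G | ≤ t_R | G1 |
| ≤ t_G | ≤ t_R | early/mid S |
| ≤ t_G | > t_R | late S |

Nuclear and EdU masks follow the original Fiji chains (rolling-ball
background subtraction r = 100 px, CLAHE with block 127 / 256 bins /
slope 3, Otsu or Moments auto-thresholds, Gaussian blur σ = 2 for EdU).
Downstream statistics: per-phase marker means normalized across phases,
pouch-to-hinge 15 × 15 µm ROI intensity ratios, EdU/DAPI area fractions,
mean intensities and region areas. A synthetic-disc generator with
complete ground truth (nucleus positions, phases, region masks) makes
every stage testable.

**Genomics track.** CUT&Tag regions are categorized as peaks shared
between wild type and *Cdk1*-RNAi, unique to either, or 500-bp bins with
no called peak. Counts are normalized by combined spike-in × total-H3
size factors, and each region is tested with a negative-binomial GLM
(`count ~ replicate + condition`, fixed size factors, method-of-moments
dispersion with a global median floor), discarding regions with basemean
≤ 25, adjusting p-values by Benjamini–Hochberg, and shrinking log2 fold
changes under a zero-centered normal prior. Per-category summaries
report percent significantly up/down at adjusted p < 0.1.

See `vignettes/methods.Rmd` for the full model description, parameter
meanings and design rationale.

## Worked example

```r
library(fuccidisc)

# a synthetic disc: 500 nuclei, an H3K27ac-like marker that peaks in S phase
spec <- disc_spec(
  markers = list(H3K27ac = marker_spec(phase_profile(0.85, 1.30, 1.25, 0.90),
                                       base_intensity = 100)),
  seed = 1)
d <- generate_disc(spec)

# segment, derive FUCCI thresholds from 5 early-S nuclei, classify pixels
mask <- make_nuclear_mask(d$channels["DAPI"], "dapi_otsu")
ref  <- d$nuclei$id[d$nuclei$phase == "EARLY_S"][1:5]
thr  <- derive_thresholds(d$channels$GFP, d$channels$RFP, ref,
                          labels = d$truth_labels)
thr
#> FUCCI thresholds: GFP 16.91, RFP 16.29 (from 5 reference nuclei)

labs <- classify_pixels(d$channels$GFP, d$channels$RFP, thr, mask)
round(phase_fractions(labs), 3)
#>      G1 EARLY_S  LATE_S      G2
#>   0.334   0.045   0.250   0.371

phase_normalized_means(d$channels$H3K27ac, labs)
#>     phase n_pixels raw_mean normalized
#> 1      G1     8445     93.1      0.824
#> 2 EARLY_S     1139    132.0      1.169
#> 3  LATE_S     6328    128.1      1.135
#> 4      G2     9389     98.5      0.873
```

The thresholds sit at the early-S reporter level (≈ 15 a.u. + background),
as the derivation rule dictates. The *area* fractions differ from the
*nucleus* proportions the generator used (0.3/0.2/0.2/0.3) in a
characteristic way: early-S nuclei are FUCCI-negative, so under noise
their pixels scatter across the threshold quadrants and the early-S area
fraction is underestimated — an intrinsic property of the per-pixel rule
discussed in the vignette. The phase-normalized marker profile
nevertheless recovers the generator's S-phase-peaked profile
(0.85/1.30/1.25/0.90 rescaled to mean 1 is 0.79/1.21/1.16/0.84): the
early-S class stays pure, ranks are preserved, and each value lands
within 0.05 of its target.

The genomics track, end to end:

```r
cs <- generate_counts(count_sim_spec(
  true_lfc = c(shared = 1, unique_wt = 0, unique_kd = 0, no_peak_bin = 0),
  seed = 1))
sf  <- compute_size_factors(cs$sample_info$spikein_total, cs$h3_counts)
res <- nb_differential(cs$counts, cs$sample_info, sf, regions = cs$regions)
summarize_categories(res)
```

`run_pipeline(run_config(list(seed = 1)), "out/")` chains both tracks and
writes provenance-headed TSVs plus TIFF masks;
`inst/scripts/fuccidisc-cli.R` exposes the same stages as shell
subcommands.

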