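---
title: "Methods: FUCCI phase classification and quantitative histone-mark analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FUCCI phase classification and quantitative histone-mark analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuccidisc)
```

## Scope

`fuccidisc` re-implements, as tested code, a quantitative workflow for
studying how cell-cycle dynamics shape histone post-translational
modifications in the *Drosophila* wing imaginal disc. Two tracks are
covered:

* an **imaging track** — nuclear and EdU mask construction, per-pixel
  FUCCI cell-cycle phase classification, and phase-resolved or
  compartment-resolved intensity statistics (pouch vs hinge ratios,
  EdU/DAPI area fractions, phase-normalized marker profiles);
* a **genomics track** — CUT&Tag region categorization (peaks shared
  between wild type and *Cdk1* knockdown, unique to either, or 500-bp bins
  with no called peak), spike-in plus total-H3 normalization, and a
  negative-binomial differential test with replicate correction,
  Benjamini–Hochberg adjustment and normal-prior log2 fold-change
  shrinkage.

Because the microscopy and sequencing data themselves are not required for
validating the computations, both tracks are driven by synthetic-data
generators with complete ground truth. The generators are first-class,
tested components, and everything downstream is validated against the
quantities they encode.

## The synthetic wing disc

`generate_disc()` renders a multi-channel field (DAPI, FUCCI-GFP,
FUCCI-RFP, plus any number of marker channels) of hard-disc nuclei with a
per-nucleus cell-cycle phase. Channel values follow a fully explicit
generative formula — background + per-nucleus contribution + additive
Gaussian noise clipped at zero — so noise-free channels are exactly
predictable, which the unit tests exploit.

Key choices, with rationale:

* **Geometry.** The default field is 384 × 384 px at 0.5 µm/px (a
  192 µm square), with a central 32-gon "pouch" and a surrounding annular
  "hinge", the two compartments of interest. 500 nuclei of radius
  2.0 ± 0.2 µm are placed on a jittered hexagonal lattice restricted to
  the compartments, with hard-disc non-overlap enforced. The lattice
  emulates the dense, near-crystalline packing of the disc epithelium;
  plain uniform rejection sampling at comparable packing fractions both
  jams and produces local density fluctuations much larger than real
  tissue shows, which would dominate any 15 × 15 µm ROI statistic. When
  fewer nuclei than lattice sites are requested, sites are thinned
  systematically along a serpentine path so density stays spatially
  uniform. A request that exceeds the available sites raises a
  "geometry too dense" error.
* **Phases.** Per-nucleus phases default to exact largest-remainder
  allocation of the requested proportions (shuffled with the seed), so a
  500-nucleus disc realizes the study proportions it was asked for;
  `phase_sampling = "multinomial"` gives i.i.d. sampling for
  distribution-level properties.
* **FUCCI scheme.** The reporters encode G1 (GFP high / RFP low), early S
  (both low), late S (GFP low / RFP high) and G2 (both high). The default
  intensities separate three levels: *off* (5 a.u., reporter fully
  degraded), *early-S residual* (15 a.u.) and *expressed* (100 a.u.).
  The distinction between "off" and "early-S residual" matters: phase
  thresholds are derived *from early-S nuclei*, so they sit at the
  early-S level. If every "low" state sat at that same level (a single
  low value), any amount of noise would scatter half of the G1 pixels'
  RFP values above the threshold and misclassify them — the threshold
  would coincide exactly with the mean of the distribution it is supposed
  to bound. With the off level below the early-S residual, thresholds
  retain a margin of two noise standard deviations at the default noise
  (5 a.u., 5 % of the expressed level). At zero noise all phases separate
  exactly, since boundary equality is assigned to the "≤" branch of the
  classification rule.
* **Markers.** Each marker channel has a base intensity, a per-phase
  multiplier profile (e.g., an acetylation mark that peaks in S phase)
  and a pouch multiplier modeling compartment-restricted genetic
  manipulation. DAPI is constant per nucleus by default; an optional
  ramp scales it with DNA content across S phase.
* **Noise.** Additive Gaussian, clipped at zero, identical for all
  channels. The imaging noise of the original data is not documented, so
  the default (5 a.u.) is a free parameter chosen to be clearly visible
  (5 % of the expressed FUCCI level) without overwhelming the reporter
  scheme.

What the generator deliberately does **not** emulate: photorealistic
point-spread functions, intensity gradients with depth, mitotic figures
(mitotic cells are excluded from the original analysis), nucleus shape
irregularity, or touching/overlapping nuclei. Passing tests therefore
demonstrate the correctness of the computations under a clean generative
model, not robustness to every imaging artifact of real discs.

## Segmentation

The mask chains mirror the Fiji workflows used in the original analysis:

* `rolling_ball_subtract(image, radius = 100)` — background estimated as
  the grayscale morphological opening with a flat disc of the given
  radius, subtracted and clipped at zero. The contract is
  "flat-background removal at structuring radius r"; a constant image
  maps to zero and features smaller than the radius are preserved.
* `clahe(image, block_size = 127, n_bins = 256, max_slope = 3)` —
  contrast-limited adaptive histogram equalization. The block size is
  interpreted as the tile edge length in pixels (tile counts are
  `round(dim / block_size)`, at least one); implementations differ subtly
  in this parameterization and this reading is documented rather than
  claimed canonical. Intensities are equalized on a min–max-scaled copy
  and mapped back, so output stays in the input's intensity convention; a
  constant image is returned unchanged.
* `auto_threshold(image, method)` — Otsu (maximum between-class variance)
  or Moments (Tsai's moment-preserving threshold), computed on a 256-bin
  histogram spanning the observed range, matching 8-bit tool behavior
  while accepting floating-point input. Both are validated against
  brute-force oracles, exactly, on random histograms. A constant image is
  an error (the threshold is undefined). A caveat worth knowing: on an
  exactly symmetric two-delta histogram the Moments threshold is
  degenerate (any split preserves the moments) and the cumulative rule
  returns the top bin.
* Presets: `dapi_moments` and `dapi_otsu` (subtract background r = 100 →
  CLAHE 127/256/3 → threshold), used for EdU quantification and phase
  scoring respectively, are kept distinct rather than unified because the
  original workflows differ exactly in the thresholding method.
  `averaged_otsu` (sequential pairwise averaging of the nuclear channels →
  Otsu) reproduces the phase-resolved marker workflow. `make_edu_mask`
  is Gaussian blur (σ = 2 px) followed by a Moments threshold.
* Polygon regions are rasterized by the even-odd rule with pixel centers;
  `intersect_masks` is the binary AND used to restrict masks to the
  manually outlined pouch.

## FUCCI phase classification

One threshold pair per disc: the GFP and RFP thresholds are the average
reporter intensity of *k* = 5 reference nuclei in early S phase. The
package averages per-nucleus means (robust to nucleus size variation);
pooled-pixel averaging is available, since the original description does
not distinguish the two. Reference nuclei are supplied explicitly (ids or
masks); `select_reference_nuclei()` is a convenience extension that picks
the *k* nuclei with lowest combined reporter signal.

Every nuclear pixel is then classified: G2 if GFP > t and RFP > t; G1 if
GFP > t and RFP ≤ t; early/mid S if both ≤ t; late S if GFP ≤ t and
RFP > t. Ties go to "≤" exactly as stated. The four rules partition the
(GFP, RFP) plane, so classification is total on the mask.

A consequence of deriving thresholds from the FUCCI-negative (early-S)
population is that, under noise, individual pixels of genuinely negative
nuclei fall on either side of the threshold in each channel — the
threshold *is* the mean of their distribution. Per-pixel labels of
early-S nuclei are therefore intrinsically noisy at any positive noise
level, while nucleus-level majority votes and phase-aggregated statistics
remain accurate; the noise-free limit classifies every pixel exactly.
The package's tests check the EdU cross-validation property (EdU-positive
pixels classified as S phase) in that noise-free limit and check the
phase-profile statistics, which tolerate the scatter, at realistic noise.

## Quantification

* **Phase-normalized profiles** (`phase_normalized_means`). Raw value =
  mean marker intensity over a phase's pixels. Two normalizations are
  exposed because the source describes both: `mean_of_phases` (divide by
  the average of the four phase means; values average to 1) — the
  default, matching the "average fluorescence intensity across all
  phases" wording — and `sum_of_phases` (divide by their sum; values are
  the relative contribution of each phase). Which convention produced
  the published panels is not resolvable from the text; the choice only
  rescales profiles by a constant factor of 4.
* **ROI ratios** (`roi_ratio`). Mean of numerator-ROI means over mean of
  denominator-ROI means, on 15 × 15 µm squares — the pouch/hinge,
  ZNC in/out, and patch/adjacent statistics. ROI placement is an input;
  `place_rois()` is a seeded fixture helper that keeps an 8-px margin
  from compartment borders, standing in for careful manual placement. In
  the pipeline the compartment ratio is measured after subtracting the
  channel's constant imaging offset (`estimate_background()`, the median
  extra-nuclear intensity): a constant offset otherwise dilutes every
  compartment ratio toward 1 by a factor that depends on the offset-to-
  signal ratio.
* **Area fractions** (`area_fraction`). The EdU/DAPI statistic divides
  the EdU-positive area by the area of "EdU and DAPI positive" support;
  this is read as the union of the two masks, which bounds the statistic
  in [0, 1]; an intersection-denominator variant is behind a flag.
* `mean_intensity` and `region_area` are the plain OPP-level and
  pouch-size measurements (mask/ROI mean; rasterized polygon pixel count
  × pixel area). `dapi_normalize` divides a marker ratio by the matching
  DAPI ratio where nuclear-density correction is wanted.

## CUT&Tag differential quantification

Coordinates are BED-style 0-based half-open throughout.

* **Tiling and categories.** `tile_genome` produces 500-bp bins covering
  each chromosome (terminal bins truncated). `categorize_regions` merges
  the union of both conditions' peaks and labels each merged peak
  `shared` when it overlaps (≥ 1 bp — the simplest reproducible rule, the
  source states none) a peak from each condition, else `unique_wt` /
  `unique_kd`; bins overlapping no peak become `no_peak_bin`. Truncated
  terminal bins are excluded so no-peak bins are exactly 500 bp.
  Categories are disjoint by construction and the whole operation is
  validated against a quadratic brute-force oracle.
* **Normalization.** Two multiplicative components per sample: a
  spike-in factor proportional to the sample's exogenous lambda fragment
  total, and an H3 factor — the median-of-ratios size factor of the
  matched total-H3 profile (matched explicitly via the sample sheet, no
  implicit pairing). The exact composition used by the original external
  normalization code is not specified; this product-of-factors scheme is
  a declared stand-in. The spike-in component defaults to a **fixed
  reference** (1000 fragments) rather than the geometric mean of the
  observed totals: with a fixed reference, multiplying one sample's
  counts and its spike-in total by any constant leaves its normalized
  counts exactly unchanged (pure depth effects cancel), whereas
  geometric-mean centring couples every factor to every total and breaks
  that invariance by a factor c^(1/n). Geometric-mean centring remains
  available (`center = "geomean"`) for reporting factors centred around 1.
* **Differential test** (`nb_differential`). Normalized counts = raw /
  combined factor; regions with basemean ≤ 25 are discarded before
  testing. Each region gets an NB GLM `count ~ replicate + condition`
  with log link and log size factors as offset — the replicate covariate
  is a fixed-effect factor, the size factors are fixed, never
  re-estimated. The dispersion is a per-region method-of-moments
  estimate, floored at the median of the raw per-region estimates across
  all tested regions (and 1e-8 absolutely). The global floor is the one
  piece of moderation applied: a moment estimate from two replicates per
  condition underestimates the dispersion half the time, and using it
  unmoderated inflates Wald statistics enough to push the null
  discovery fraction above the nominal 0.1 — the reference
  implementation solves this with dispersion-trend shrinkage, which is
  deliberately not replicated here because the analysis conclusions rest
  on direction and aggregate behavior, not the exact dispersion
  machinery. Wald p-values on the condition coefficient are BH-adjusted
  across the full tested region set of a mark (one differential run per
  mark, not per category).
* **Shrinkage.** Normal-prior log2 fold-change shrinkage: the prior is a
  zero-centered Gaussian whose scale is matched to the upper 5 % quantile
  of the raw estimates, and the shrunken estimate is the posterior mean
  under the Gaussian approximation of the likelihood,
  `lfc × σ²_prior / (σ²_prior + se²)`. This is contractive by
  construction (|shrunk| ≤ |raw| for every region).
* **Summaries.** `summarize_categories` reports, per region category, the
  number tested and the percentage significantly up (LFC > 0) or down
  (LFC < 0) at adjusted p < 0.1.

Simulated calibration at the default study conditions (baseline mean 200,
dispersion 0.05, 2 + 2 replicates, 2000 regions): the null discovery
fraction is ~0.001, a true log2 fold change of +1 is estimated with bias
below 0.02, and the power to call |LFC| = 1 at adjusted p < 0.1 is about
0.65–0.70 — two replicates per condition with honest, uncorrelated
dispersion estimates simply do not support more, and the test suite
records that level as the regression value.

## Pipeline, formats, determinism

`run_config()` validates a nested configuration (YAML file or list)
against the full default set — unknown keys are rejected by name — with
every default equal to the analysis parameter where one exists (rolling
ball 100 px, CLAHE 127/256/3, bins 500 bp, basemean cutoff 25, α = 0.1,
k = 5 reference nuclei). `run_pipeline()` chains
simulate → segment → classify → quantify plus the count track, writing
TSVs with a provenance header (package version + configuration hash,
no timestamps) and TIFF images/masks (32-bit float channels, 8-bit
masks and label maps). Given a seed, two runs are byte-identical. A thin
command-line wrapper (`inst/scripts/fuccidisc-cli.R`) exposes
`simulate-disc`, `simulate-counts`, `segment`, `classify`, `quantify`,
`cuttag-diff` and `run` subcommands over the same functions.

Problem sizes used by the test suite and the acceptance script — 384-px
discs with 500 nuclei, 10 discs per recovery experiment, 2000 regions
and 5 seeds for the null simulation, 500 random instances for the
interval oracle — were chosen as the smallest sizes at which the
Monte-Carlo error of each recovered quantity is comfortably below its
assertion tolerance.

## Known limitations

* The synthetic disc is a clean generative model (see above); real-disc
  robustness (clumped nuclei, uneven illumination, z-projection
  artifacts) is out of scope.
* Per-pixel phase labels of FUCCI-negative nuclei are intrinsically noisy
  under the early-S-derived threshold rule (discussed above).
* The dispersion model is deliberately simpler than the reference
  differential implementation; per-region significance on real data will
  differ in detail even where aggregate behavior agrees.
* Peak calling, read alignment and coverage-track rendering are consumed
  as inputs or out of scope entirely.
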