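Package: fuccidisc
Title: FUCCI Cell-Cycle Phase Classification and Histone-Modification
    Quantification in Wing Imaginal Discs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a quantitative imaging and
    epigenomics workflow for cell cycle-linked histone-modification dynamics
    in the Drosophila wing imaginal disc. Provides a synthetic wing-disc
    image generator with known ground truth (nuclei, FUCCI reporter
    intensities, per-phase marker profiles, pouch/hinge regions), the
    nuclear- and EdU-mask segmentation chains (rolling-ball background
    subtraction, CLAHE, Otsu and Moments auto-thresholding), per-pixel
    four-phase FUCCI classification from early-S-derived reporter
    thresholds, phase-normalized and region-of-interest intensity
    statistics, and a CUT&Tag track: genome tiling, peak-category
    assignment (shared/unique/no-peak bins), spike-in plus histone-H3
    normalization, and negative-binomial differential enrichment with
    Benjamini-Hochberg adjustment and normal-prior log2 fold-change
    shrinkage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    MASS,
    methods,
    stats,
    utils,
    tools,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
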