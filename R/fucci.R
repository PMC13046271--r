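#' FUCCI phase classification
#'
#' The FUCCI reporter pair (a degradable GFP-tagged E2F1 fragment and an
#' RFP-tagged CycB fragment) encodes cell-cycle phase in the joint
#' presence/absence of the two fluorophores: G1 is GFP-high/RFP-low, early
#' S has both reporters degraded, late S is GFP-low/RFP-high and G2 has
#' both high. One threshold pair per disc is derived from reference nuclei
#' in early S phase and every nuclear pixel is classified by comparing its
#' GFP and RFP intensity against these thresholds.
#'
#' @name fucci
NULL

#' Phase level names, in order G1, early S, late S, G2
#' @export
PHASES <- c("G1", "EARLY_S", "LATE_S", "G2")

#' Derive FUCCI intensity thresholds from reference early-S nuclei
#'
#' The GFP (resp. RFP) threshold is the average reporter intensity of the
#' reference nuclei. By default each nucleus contributes its mean pixel
#' intensity and the nucleus means are averaged (robust to nucleus-size
#' variation); `method = "pooled_pixels"` instead averages all reference
#' pixels in one pool.
#'
#' @param gfp,rfp 2-D numeric matrices (reporter channels).
#' @param reference_nuclei list of logical masks, one per reference nucleus;
#'   or, when `labels` is given, an integer vector of nucleus label ids.
#' @param labels optional integer label image used to resolve ids.
#' @param method `"nucleus_means"` (default) or `"pooled_pixels"`.
#' @return object of class `phase_thresholds` with fields `gfp_threshold`,
#'   `rfp_threshold`, `n_reference_nuclei`.
#' @export
derive_thresholds <- function(gfp, rfp, reference_nuclei, labels = NULL,
                              method = c("nucleus_means", "pooled_pixels")) {
  assert_image(gfp, "gfp"); assert_image(rfp, "rfp")
  method <- match.arg(method)
  if (!is.null(labels)) {
    ids <- as.integer(reference_nuclei)
    reference_nuclei <- lapply(ids, function(id) labels == id)
  }
  if (length(reference_nuclei) < 1L) stop("empty reference set")
  sizes <- vapply(reference_nuclei, sum, numeric(1))
  if (any(sizes == 0)) stop("reference nucleus with empty mask")
  if (method == "nucleus_means") {
    gfp_t <- mean(vapply(reference_nuclei, function(m) mean(gfp[m]), numeric(1)))
    rfp_t <- mean(vapply(reference_nuclei, function(m) mean(rfp[m]), numeric(1)))
  } else {
    pool <- Reduce(`|`, reference_nuclei)
    gfp_t <- mean(gfp[pool]); rfp_t <- mean(rfp[pool])
  }
  structure(list(gfp_threshold = gfp_t, rfp_threshold = rfp_t,
                 n_reference_nuclei = length(reference_nuclei)),
            class = "phase_thresholds")
}

#' @export
print.phase_thresholds <- function(x, ...) {
  cat(sprintf("FUCCI thresholds: GFP %.4g, RFP %.4g (from %d reference nuclei)\n",
              x$gfp_threshold, x$rfp_threshold, x$n_reference_nuclei))
  invisible(x)
}

#' Convenience: pick the k nuclei with lowest combined reporter signal
#'
#' An optional helper (an extension of the manual procedure, which uses
#' explicitly chosen nuclei): candidates for early S phase are the nuclei
#' with the lowest summed mean GFP + RFP.
#'
#' @param gfp,rfp reporter channels.
#' @param labels integer label image.
#' @param k number of nuclei (default 5).
#' @return integer vector of label ids.
#' @export
select_reference_nuclei <- function(gfp, rfp, labels, k = 5) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(ids) < k) stop("fewer nuclei than requested")
  score <- vapply(ids, function(id) {
    m <- labels == id
    mean(gfp[m]) + mean(rfp[m])
  }, numeric(1))
  ids[order(score)][seq_len(k)]
}

#' Classify nuclear pixels into cell-cycle phases
#'
#' Applies, to every pixel of the nuclear mask, the four-quadrant rule with
#' boundary equality going to the `<=` branch:
#' G2 if GFP > t and RFP > t; G1 if GFP > t and RFP <= t; early/mid S if
#' both <= t; late S if GFP <= t and RFP > t (each channel against its own
#' threshold). Pixels outside the mask are unassigned.
#'
#' @param gfp,rfp reporter channels.
#' @param thresholds a [derive_thresholds()] result (or a list with
#'   `gfp_threshold` and `rfp_threshold`).
#' @param nuclear_mask logical matrix of the same shape.
#' @return a `phase_label_map`: integer matrix with codes 0 = unassigned,
#'   1 = G1, 2 = early S, 3 = late S, 4 = G2, and attributes `phases`
#'   (level names) and `provenance`.
#' @export
classify_pixels <- function(gfp, rfp, thresholds, nuclear_mask) {
  assert_image(gfp, "gfp"); assert_image(rfp, "rfp")
  if (!identical(dim(gfp), dim(rfp)) || !identical(dim(gfp), dim(nuclear_mask)))
    stop("gfp, rfp and nuclear_mask shapes differ")
  g_hi <- gfp > thresholds$gfp_threshold
  r_hi <- rfp > thresholds$rfp_threshold
  labels <- matrix(0L, nrow(gfp), ncol(gfp))
  labels[nuclear_mask & g_hi & !r_hi] <- 1L   # G1
  labels[nuclear_mask & !g_hi & !r_hi] <- 2L  # early/mid S
  labels[nuclear_mask & !g_hi & r_hi] <- 3L   # late S
  labels[nuclear_mask & g_hi & r_hi] <- 4L    # G2
  structure(labels, phases = PHASES, class = "phase_label_map",
            provenance = attr(nuclear_mask, "provenance") %||% "mask")
}

#' Per-phase area fractions of a label map
#'
#' @param labels a `phase_label_map`.
#' @return named numeric 4-vector (fractions of labeled pixels) summing to 1.
#' @export
phase_fractions <- function(labels) {
  n <- tabulate(labels[labels > 0L], nbins = 4L)
  total <- sum(n)
  if (total == 0L) stop("no labeled pixels")
  stats::setNames(n / total, PHASES)
}
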