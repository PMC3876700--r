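#' Hysteresis thresholding parameters
#'
#' Thresholds are not fixed intensities but fractions of the image: the high
#' threshold is set so that `high_fraction` of the pixels exceed it (sure
#' vessel seeds), the low threshold so that `low_fraction` do (potential
#' vessel pixels). This percent-of-pixels rule makes binarization robust to
#' global intensity shifts between images; the fractions are per-protocol
#' settings since the vessel/background ratio depends on field of view.
#' Defaults 0.02 / 0.12 reflect that roughly 15% of a fundus frame is vessel.
#'
#' @param high_fraction Fraction in (0, 1) of pixels above the high threshold.
#' @param low_fraction Fraction in (0, 1), strictly greater than
#'   `high_fraction`.
#' @return A `hysteresis_params` list (connectivity fixed at 8).
#' @export
hysteresis_params <- function(high_fraction = 0.02, low_fraction = 0.12) {
  stopifnot(high_fraction > 0, low_fraction < 1,
            high_fraction < low_fraction)
  structure(list(high_fraction = high_fraction, low_fraction = low_fraction,
                 connectivity = 8L), class = "hysteresis_params")
}

#' Threshold for a target fraction of segmented pixels
#'
#' Returns the value `t` such that at least `fraction * N` pixels of the map
#' are `>= t` (the `ceil(fraction * N)`-th largest value). On a constant map
#' every value equals that constant, so the threshold does too and the caller
#' faces an all-or-nothing binarization.
#'
#' @param v A `vesselness_map` or numeric matrix.
#' @param fraction Target fraction in (0, 1).
#' @return A single threshold value.
#' @export
fraction_to_threshold <- function(v, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  x <- as.vector(.v0(v))
  k <- length(x) - max(1L, as.integer(ceiling(fraction * length(x)))) + 1L
  sort(x, partial = k)[k]
}

#' Hysteresis (double-threshold) binarization
#'
#' Canny-style: pixels above the high threshold are vessel seeds; pixels
#' between the two thresholds are kept only when 8-connected to a seed
#' through other above-low pixels. This recovers thin vessels and vessel
#' boundaries whose contrast falls below any single usable threshold, without
#' admitting isolated background noise.
#'
#' @param v A `vesselness_map` or numeric matrix.
#' @param p A [hysteresis_params()] object.
#' @return Integer 0/1 matrix with attributes `t_high`, `t_low` (the
#'   resolved threshold values).
#' @export
hysteresis_threshold <- function(v, p = hysteresis_params()) {
  vm <- .v0(v)
  t_high <- fraction_to_threshold(vm, p$high_fraction)
  t_low <- fraction_to_threshold(vm, p$low_fraction)
  low <- .as_mask(vm >= t_low)
  high <- vm >= t_high
  lab <- .label_components_cpp(low, 8L)
  keep <- unique(lab[high & low == 1L])
  out <- .as_mask(low == 1L & lab %in% keep)
  attr(out, "t_high") <- t_high
  attr(out, "t_low") <- t_low
  out
}
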