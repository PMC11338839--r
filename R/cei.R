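#' Configuration for the Cognitive Effort Index
#'
#' Defaults are the marker's defining constants: delta band 1-4 Hz, 10 s
#' segments split into 20 epochs of 500 ms, middle band `[1/3, 2/3]`
#' (closed on both ends), exclusion of segments whose SD/mean ratio
#' exceeds 1.
#'
#' @param band Delta band (Hz).
#' @param segment_s Segment length (s).
#' @param epochs_per_segment Number of epochs per segment.
#' @param middle_band Closed interval defining "effective effort" CEI values.
#' @param middle_inclusive Include the interval endpoints (default TRUE).
#' @param exclusion_threshold SD/mean ratio above which a segment is
#'   excluded as noisy (default 1).
#' @param filter Filter realization passed to [bandpass()].
#' @return A list of class `cei_config`.
#' @export
cei_config <- function(band = delta_band(), segment_s = 10,
                       epochs_per_segment = 20L,
                       middle_band = c(1 / 3, 2 / 3), middle_inclusive = TRUE,
                       exclusion_threshold = 1, filter = "butter") {
  stopifnot(segment_s > 0, epochs_per_segment >= 2,
            length(middle_band) == 2L, middle_band[1] < middle_band[2])
  structure(list(band = band, segment_s = segment_s,
                 epoch_s = segment_s / epochs_per_segment,
                 epochs_per_segment = as.integer(epochs_per_segment),
                 middle_band = middle_band, middle_inclusive = middle_inclusive,
                 exclusion_threshold = exclusion_threshold, filter = filter),
            class = "cei_config")
}

#' CEI of one segment from its 20 epoch powers
#'
#' The ratio of the population standard deviation to the mean of the epoch
#' powers. Ratios above the exclusion threshold (1) mark the segment as
#' noisy and excluded; an all-zero segment (mean 0) is excluded as flat.
#' Scale-invariant: `cei(c * powers) == cei(powers)` for `c > 0`.
#'
#' @param powers Numeric vector of exactly `epochs_per_segment` nonnegative
#'   epoch powers.
#' @param config A [cei_config()].
#' @return A list: `value` (SD/mean, NA when excluded), `excluded`
#'   (logical), `reason` (`NA`, `"noisy"`, or `"flat"`).
#' @export
cei_from_epoch_powers <- function(powers, config = cei_config()) {
  if (length(powers) != config$epochs_per_segment)
    stop("expected ", config$epochs_per_segment, " epoch powers, got ",
         length(powers))
  if (any(!is.finite(powers)) || any(powers < 0))
    stop("epoch powers must be finite and nonnegative")
  m <- mean(powers)
  if (m == 0)
    return(list(value = NA_real_, excluded = TRUE, reason = "flat"))
  ratio <- sqrt(mean((powers - m)^2)) / m
  if (ratio > config$exclusion_threshold)
    return(list(value = NA_real_, excluded = TRUE, reason = "noisy"))
  list(value = ratio, excluded = FALSE, reason = NA_character_)
}

#' Per-segment CEI series over the test window
#'
#' Pipeline per segment: delta band-pass, 20 epoch powers (rectified
#' integral), SD/mean ratio. Each segment is filtered independently, so the
#' series has no cross-segment state.
#'
#' @param rec An [eeg_recording()].
#' @param config A [cei_config()].
#' @return A data.frame with one row per segment: `segment` (0-based),
#'   `t_start_s`, `cei` (NA when excluded), `excluded`, `reason`.
#' @export
compute_cei_series <- function(rec, config = cei_config()) {
  segs <- segment_test_window(rec, config$segment_s)
  rows <- lapply(segs, function(sg) {
    p <- segment_epoch_powers(sg$samples, rec$fs, config$band,
                              config$epochs_per_segment, config$filter)
    r <- cei_from_epoch_powers(p, config)
    data.frame(segment = sg$index, t_start_s = sg$t_start_s,
               cei = r$value, excluded = r$excluded, reason = r$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cei_series", "data.frame")
  out
}

#' Fraction of valid CEI points in the middle third
#'
#' `%CEIm` as a fraction: the number of non-excluded CEI points inside the
#' middle band, divided by the number of non-excluded points. Excluded
#' (noisy/flat) segments returned no value and are not part of the CEI
#' sample. Missing (NA) when no valid point exists.
#'
#' @param series A `cei_series` data.frame (or numeric vector of CEI values
#'   with NA for excluded points).
#' @param config A [cei_config()] supplying the middle band and its
#'   endpoint rule.
#' @return Fraction in `[0, 1]`, or NA when the series has no valid point.
#' @export
percent_cei_middle <- function(series, config = cei_config()) {
  v <- if (is.data.frame(series)) series$cei[!series$excluded] else series[!is.na(series)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    warning("no valid CEI points; %CEIm is missing")
    return(NA_real_)
  }
  lo <- config$middle_band[1]; hi <- config$middle_band[2]
  inside <- if (config$middle_inclusive) v >= lo & v <= hi else v > lo & v < hi
  sum(inside) / length(v)
}

# Middle-band gate used for the TensI baseline: TRUE where a segment's CEI
# is valid and inside the middle band.
cei_middle_gate <- function(series, config = cei_config()) {
  lo <- config$middle_band[1]; hi <- config$middle_band[2]
  v <- series$cei
  ok <- !series$excluded & !is.na(v)
  inside <- if (config$middle_inclusive) v >= lo & v <= hi else v > lo & v < hi
  ok & inside & !is.na(inside)
}
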