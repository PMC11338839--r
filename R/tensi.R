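#' Configuration for the Tension Index
#'
#' Defaults: high-beta band 23-30 Hz, baseline gate = segments whose CEI is
#' in the middle third, high-TensI threshold 2/3 (strict), noisy (excluded
#' CEI) segments still receive a TensI value but never extend the baseline.
#'
#' @param band High-beta band (Hz).
#' @param high_threshold Strict threshold defining "high" TensI points.
#' @param skip_noisy If TRUE, segments with excluded CEI get no TensI value
#'   (stricter reading); default FALSE.
#' @param filter Filter realization passed to [bandpass()].
#' @return A list of class `tensi_config`.
#' @export
tensi_config <- function(band = high_beta_band(), high_threshold = 2 / 3,
                         skip_noisy = FALSE, filter = "butter") {
  stopifnot(high_threshold > 0, high_threshold < 1)
  structure(list(band = band, high_threshold = high_threshold,
                 skip_noisy = skip_noisy, filter = filter),
            class = "tensi_config")
}

#' TensI of one segment given the running baseline mean
#'
#' The segment's high-beta power divided by the mean beta power of the
#' baseline segments preceding it, halved, clamped to 1. Equal power and
#' baseline gives exactly 0.5; power at or beyond twice the baseline clamps
#' to 1. Undefined (NA) while no baseline segment has been seen.
#'
#' @param segment_beta_power Nonnegative beta power of the segment (uV*s).
#' @param baseline_mean Running mean beta power of preceding baseline
#'   segments, or NA when none exist yet.
#' @return Value in `[0, 1]`, or NA when the baseline is absent.
#' @export
tensi_value <- function(segment_beta_power, baseline_mean) {
  if (is.na(baseline_mean) || baseline_mean <= 0) return(NA_real_)
  min(1, (segment_beta_power / baseline_mean) / 2)
}

# --- causal running-baseline state -----------------------------------------
# The state keeps (n, sum); the exposed mean is sum / n. Addition order is
# the arrival order, so the incremental path and the batch (cumulative sum)
# path produce bit-identical values.

#' Streaming TensI: initialize state
#' @return Opaque state for [tensi_stream_step()].
#' @export
tensi_stream_init <- function() {
  list(n = 0L, sum = 0)
}

#' Streaming TensI: process one segment
#'
#' Emits the segment's TensI from the baseline accumulated so far, then --
#' only if the segment is baseline-gated (CEI in the middle third) -- adds
#' its power to the baseline. A segment never enters its own baseline.
#'
#' @param state State from [tensi_stream_init()] or a previous step.
#' @param beta_power The segment's high-beta power.
#' @param is_baseline Logical: does this segment's CEI gate it into the
#'   baseline?
#' @return List with `state` (updated), `tensi` (value or NA),
#'   `baseline_mean`, `baseline_n` (both as of emission, before update).
#' @export
tensi_stream_step <- function(state, beta_power, is_baseline) {
  bm <- if (state$n > 0L) state$sum / state$n else NA_real_
  val <- tensi_value(beta_power, bm)
  out <- list(tensi = val, baseline_mean = bm, baseline_n = state$n)
  if (isTRUE(is_baseline)) {
    state$sum <- state$sum + beta_power
    state$n <- state$n + 1L
  }
  out$state <- state
  out
}

# Batch TensI from per-segment beta powers and baseline gates. The running
# sum is accumulated with one double-precision addition per gated segment --
# the same arithmetic, in the same order, as the streaming state machine --
# so batch and stream agree bit for bit.
tensi_points_from_powers <- function(beta_powers, gate) {
  stopifnot(length(beta_powers) == length(gate))
  n_seg <- length(beta_powers)
  tensi <- numeric(n_seg); bmean <- numeric(n_seg); bn <- integer(n_seg)
  s <- 0; n <- 0L
  for (k in seq_len(n_seg)) {
    bm <- if (n > 0L) s / n else NA_real_
    bn[k] <- n; bmean[k] <- bm
    tensi[k] <- tensi_value(beta_powers[k], bm)
    if (isTRUE(gate[k])) { s <- s + beta_powers[k]; n <- n + 1L }
  }
  list(tensi = tensi, baseline_mean = bmean, baseline_n = bn)
}

#' Per-segment TensI series over the test window
#'
#' Single causal forward pass: for segment k the TensI is the ratio of its
#' high-beta power to the mean beta power of the baseline segments with
#' index < k (those whose CEI fell in the middle third), halved and clamped
#' to `[0, 1]`. The segment's own power joins the baseline only after its
#' TensI is emitted. Segments before the first baseline segment are
#' undefined (NA).
#'
#' @param rec An [eeg_recording()].
#' @param cei_series The aligned CEI series from [compute_cei_series()];
#'   computed here if NULL.
#' @param config A [tensi_config()].
#' @param cei_cfg The [cei_config()] used for the gate (and for computing
#'   `cei_series` when NULL).
#' @param stream If TRUE, replay the recording one segment at a time through
#'   the incremental state machine instead of the batch path (bit-identical
#'   result; exists so the equivalence is testable end to end).
#' @return Data.frame with one row per segment: `segment`, `t_start_s`,
#'   `beta_power`, `baseline_mean`, `baseline_n`, `tensi`, `defined`.
#' @export
compute_tensi_series <- function(rec, cei_series = NULL, config = tensi_config(),
                                 cei_cfg = cei_config(), stream = FALSE) {
  if (is.null(cei_series)) cei_series <- compute_cei_series(rec, cei_cfg)
  segs <- segment_test_window(rec, cei_cfg$segment_s)
  if (length(segs) != nrow(cei_series))
    stop("cei_series is not aligned to the segmentation")
  beta <- vapply(segs, function(sg)
    segment_band_power(sg$samples, rec$fs, config$band, config$filter),
    numeric(1))
  gate <- cei_middle_gate(cei_series, cei_cfg)

  if (stream) {
    st <- tensi_stream_init()
    vals <- numeric(length(beta)); bmean <- numeric(length(beta))
    bn <- integer(length(beta))
    for (k in seq_along(beta)) {
      stp <- tensi_stream_step(st, beta[k], gate[k])
      vals[k] <- stp$tensi; bmean[k] <- stp$baseline_mean; bn[k] <- stp$baseline_n
      st <- stp$state
    }
  } else {
    pts <- tensi_points_from_powers(beta, gate)
    vals <- pts$tensi; bmean <- pts$baseline_mean; bn <- pts$baseline_n
  }
  if (config$skip_noisy) vals[cei_series$excluded] <- NA_real_

  out <- data.frame(segment = cei_series$segment,
                    t_start_s = cei_series$t_start_s,
                    beta_power = beta, baseline_mean = bmean,
                    baseline_n = bn, tensi = vals,
                    defined = !is.na(vals))
  if (!any(out$defined))
    warning("no baseline segment in the test window; all TensI undefined")
  class(out) <- c("tensi_series", "data.frame")
  out
}

#' Fraction of defined TensI points above the high threshold
#'
#' `%TensI-high` as a fraction: defined points strictly greater than 2/3,
#' over all defined points. Undefined points (no baseline yet) are not part
#' of the TensI sample. Missing (NA) when nothing is defined.
#'
#' @param series A `tensi_series` data.frame (or numeric vector with NA for
#'   undefined points).
#' @param config A [tensi_config()] supplying the threshold.
#' @return Fraction in `[0, 1]`, or NA.
#' @export
percent_tensi_high <- function(series, config = tensi_config()) {
  v <- if (is.data.frame(series)) series$tensi else series
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    warning("no defined TensI points; %TensI-high is missing")
    return(NA_real_)
  }
  sum(v > config$high_threshold) / length(v)
}

#' Both marker summaries for one administered test
#'
#' Runs the full pipeline (segmentation, CEI series, TensI series) and
#' returns the per-test summary: `%CEIm` and `%TensI-high` as percentages.
#'
#' @param rec An [eeg_recording()].
#' @param cei_cfg,tensi_cfg Configurations.
#' @param stream Replay causally one segment at a time (see
#'   [compute_tensi_series()]).
#' @return List with `cei_series`, `tensi_series`, `summary` (list:
#'   `n_segments`, `n_valid_cei`, `n_defined_tensi`, `percent_cei_middle`,
#'   `percent_tensi_high`; percentages on the 0-100 scale, NA when missing).
#' @export
compute_markers <- function(rec, cei_cfg = cei_config(),
                            tensi_cfg = tensi_config(), stream = FALSE) {
  cei <- compute_cei_series(rec, cei_cfg)
  tensi <- suppressWarnings(
    compute_tensi_series(rec, cei, tensi_cfg, cei_cfg, stream = stream))
  pc <- suppressWarnings(percent_cei_middle(cei, cei_cfg))
  pt <- suppressWarnings(percent_tensi_high(tensi, tensi_cfg))
  list(cei_series = cei, tensi_series = tensi,
       summary = list(n_segments = nrow(cei),
                      n_valid_cei = sum(!cei$excluded),
                      n_defined_tensi = sum(tensi$defined),
                      percent_cei_middle = 100 * pc,
                      percent_tensi_high = 100 * pt))
}
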