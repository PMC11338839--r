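# Band filtering, 10 s segmentation, 500 ms epoching, and the rectified
# epoch-power operator that both markers are built on.

#' Frequency band definition
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high`.
#' @return Numeric length-2 vector of class `band_definition`.
#' @export
band_definition <- function(low_hz, high_hz) {
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz <= 0 || high_hz <= low_hz)
    stop("band must satisfy 0 < low_hz < high_hz")
  structure(c(low_hz, high_hz), class = "band_definition")
}

#' @rdname band_definition
#' @export
delta_band <- function() band_definition(1, 4)

#' @rdname band_definition
#' @export
high_beta_band <- function() band_definition(23, 30)

check_band_fs <- function(band, fs) {
  if (band[2] >= fs / 2)
    stop(sprintf("band %g-%g Hz infeasible at fs = %g Hz (Nyquist %g Hz)",
                 band[1], band[2], fs, fs / 2))
  invisible(TRUE)
}

#' Split the test window into consecutive 10 s segments
#'
#' Segments are disjoint, ordered, and cover exactly the first
#' `floor(T / segment_s) * segment_s` seconds of the test window; a trailing
#' partial window is dropped (the marker statistics assume full 20-epoch
#' segments).
#'
#' @param rec An [eeg_recording()].
#' @param segment_s Segment length in seconds (default 10).
#' @return A list of segments; each is a list with `samples` (exactly
#'   `round(segment_s * fs)` points), `index` (0-based ordinal), and
#'   `t_start_s` (segment start relative to recording start).
#' @export
segment_test_window <- function(rec, segment_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  tw <- rec$test_window
  dur <- tw[2] - tw[1]
  if (dur < segment_s - 1e-9)
    stop("test window too short: ", format(dur), " s < ", segment_s, " s")
  n_seg <- floor(dur / segment_s + 1e-9)
  seg_n <- as.integer(round(segment_s * rec$fs))
  start0 <- as.integer(round(tw[1] * rec$fs))
  lapply(seq_len(n_seg) - 1L, function(k) {
    i0 <- start0 + k * seg_n
    list(samples = rec$samples[(i0 + 1L):(i0 + seg_n)],
         index = k,
         t_start_s = tw[1] + k * segment_s)
  })
}

#' Band-pass filter a segment
#'
#' Two realizations: `"butter"`, a zero-phase forward-backward 4th-order
#' Butterworth (offline analysis; no phase distortion, so epoch boundaries
#' are not smeared), and `"fir"`, a causal linear-phase FIR of about 1 s
#' (for true sample-by-sample real-time use, at the cost of its group
#' delay). Output length equals input length in both cases.
#'
#' @param x Numeric samples.
#' @param band A [band_definition()] or length-2 numeric.
#' @param fs Sampling rate in Hz.
#' @param method `"butter"` (zero-phase, default) or `"fir"` (causal).
#' @param order Butterworth prototype order (default 4).
#' @param fir_s Causal FIR length in seconds (default 1).
#' @return Filtered samples, same length as `x`.
#' @export
bandpass <- function(x, band, fs, method = c("butter", "fir"),
                     order = 4, fir_s = 1) {
  method <- match.arg(method)
  check_band_fs(band, fs)
  w <- c(band[1], band[2]) / (fs / 2)
  if (method == "butter") {
    bf <- signal::butter(order, w, type = "pass")
    as.numeric(signal::filtfilt(bf, x))
  } else {
    ntaps <- round(fir_s * fs)
    ntaps <- ntaps + (ntaps %% 2L)  # fir1 even order -> odd-length type-I FIR
    h <- signal::fir1(ntaps, w, type = "pass")
    as.numeric(signal::filter(h, x))
  }
}

# Epoch boundaries: partition n samples into n_epochs contiguous epochs with
# rounded boundaries, so every epoch is within one sample of n / n_epochs and
# the epochs cover the segment exactly.
epoch_bounds <- function(n, n_epochs = 20L) {
  b <- round(seq(0L, n, length.out = n_epochs + 1L))
  as.integer(b)
}

#' Split a segment into 20 epochs of 500 ms
#'
#' @param x Segment samples (one 10 s segment).
#' @param n_epochs Number of epochs (default 20).
#' @return List of `n_epochs` numeric vectors partitioning `x`; each epoch
#'   is within one sample of `length(x) / n_epochs`.
#' @export
split_epochs <- function(x, n_epochs = 20L) {
  b <- epoch_bounds(length(x), n_epochs)
  lapply(seq_len(n_epochs), function(k) x[(b[k] + 1L):b[k + 1L]])
}

#' Rectified-integral power of an epoch
#'
#' The power operator used throughout: the integral of the absolute signal
#' over the epoch, `sum(abs(x)) / fs`, in uV*s. Positively homogeneous of
#' degree 1, so every ratio built on it is gain-invariant.
#'
#' @param x Epoch samples (non-empty).
#' @param fs Sampling rate in Hz.
#' @return Nonnegative scalar, uV*s.
#' @export
epoch_power <- function(x, fs) {
  if (length(x) == 0L) stop("empty epoch")
  sum(abs(x)) / fs
}

# Per-segment pipeline step: filter to band, split into epochs, return the
# epoch powers.
segment_epoch_powers <- function(seg_samples, fs, band, n_epochs = 20L,
                                 method = "butter") {
  y <- bandpass(seg_samples, band, fs, method = method)
  vapply(split_epochs(y, n_epochs), epoch_power, numeric(1), fs = fs)
}

# Band power of a whole segment (single epoch spanning it).
segment_band_power <- function(seg_samples, fs, band, method = "butter") {
  epoch_power(bandpass(seg_samples, band, fs, method = method), fs)
}
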