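#' Single-channel EEG recording
#'
#' Container for one EEG channel sampled at a fixed rate, together with the
#' test window: the interval (in seconds from recording start) during which
#' the cognitive test was administered. All downstream marker computation
#' operates on the test window only.
#'
#' @param samples Numeric vector of amplitudes in microvolts. Must be finite;
#'   recordings containing NaN/Inf runs are rejected at load.
#' @param fs Sampling rate in Hz (> 0). Rates below 64 Hz cannot resolve the
#'   23-30 Hz band and are rejected.
#' @param test_window Length-2 numeric, `c(start_s, end_s)`, offsets in
#'   seconds from recording start. Defaults to the whole recording.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `samples`, `fs`, `test_window`.
#' @export
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 2 * seq(0, 30, by = 1/128)), fs = 128)
#' rec
eeg_recording <- function(samples, fs, test_window = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("recording has no samples")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) stop("fs must be a positive number")
  if (fs < 64) stop("fs must be >= 64 Hz to resolve the 23-30 Hz band")
  duration <- length(samples) / fs
  if (is.null(test_window)) test_window <- c(0, duration)
  test_window <- as.numeric(test_window)
  if (length(test_window) != 2L || anyNA(test_window))
    stop("test_window must be c(start_s, end_s)")
  if (test_window[1] < 0 || test_window[1] >= test_window[2] ||
      test_window[2] > duration + 1e-9)
    stop("test_window must satisfy 0 <= start < end <= duration")
  structure(list(samples = samples, fs = fs, test_window = test_window),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples @ %g Hz (%.1f s), test window [%g, %g] s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$test_window[1], x$test_window[2]))
  invisible(x)
}

#' Read a recording from a two-column CSV
#'
#' Expects a header `time_s,amplitude_uv`; time is seconds from recording
#' start and must be uniformly sampled. The test window is supplied as an
#' argument (or defaults to the whole file).
#'
#' @param path CSV file path.
#' @param start_s,end_s Optional test-window bounds in seconds.
#' @return An [eeg_recording()].
#' @export
read_recording_csv <- function(path, start_s = NULL, end_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "amplitude_uv")
  if (!all(need %in% names(df)))
    stop("CSV must have columns time_s, amplitude_uv")
  tm <- df$time_s
  if (length(tm) < 2L) stop("CSV has fewer than 2 samples")
  dt <- diff(tm)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1] + 1e-9)
    stop("time_s is not uniformly sampled")
  fs <- 1 / dt[1]
  tw <- c(if (is.null(start_s)) 0 else start_s,
          if (is.null(end_s)) length(df$amplitude_uv) / fs else end_s)
  eeg_recording(df$amplitude_uv, fs, tw)
}

#' Write a recording to the two-column CSV dialect
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- data.frame(time_s = (seq_along(rec$samples) - 1) / rec$fs,
                   amplitude_uv = rec$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording (EDF/EDF+ or CSV, dispatched on extension)
#'
#' For EDF files, the channel is selected by name or 1-based index, and
#' `test_start` / `test_end` EDF+ annotations (when present) set the test
#' window unless `start_s` / `end_s` are given explicitly.
#'
#' @param path Input file (`.edf` or `.csv`).
#' @param channel Channel name or 1-based index for EDF input.
#' @param start_s,end_s Optional explicit test-window bounds (seconds);
#'   override any annotations.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, channel = 1L, start_s = NULL, end_s = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(read_recording_csv(path, start_s, end_s))
  if (ext != "edf") stop("unsupported input format: .", ext)
  edf <- read_edf(path)
  sig <- select_edf_signal(edf, channel)
  tw <- NULL
  ann <- edf$annotations
  if (!is.null(ann) && nrow(ann) > 0) {
    ts <- ann$onset[ann$label == "test_start"]
    te <- ann$onset[ann$label == "test_end"]
    if (length(ts) == 1L && length(te) == 1L) tw <- c(ts, te)
  }
  if (!is.null(start_s) || !is.null(end_s)) {
    dur <- length(sig$samples) / sig$fs
    tw <- c(if (is.null(start_s)) 0 else start_s,
            if (is.null(end_s)) dur else end_s)
  }
  eeg_recording(sig$samples, sig$fs, tw)
}
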