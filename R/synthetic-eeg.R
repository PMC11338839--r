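# Seeded synthetic single-channel EEG with controllable marker-relevant
# structure: a delta (1-4 Hz) component whose sinusoidal amplitude-envelope
# modulation depth drives the CEI, a high-beta (23-30 Hz) component whose
# burst gain drives the TensI, a pink broadband floor, and optional artifact
# spikes. The delta and beta carriers are amplitude-flattened band-limited
# Gaussian noise (divided by their smoothed Hilbert envelope), so the
# applied envelope -- not the carrier's own fluctuation -- controls the
# epoch-power variability.

#' Synthetic EEG generator specification
#'
#' @param duration_s Recording duration in seconds.
#' @param fs Sampling rate (default 128 Hz, the conventional single-channel
#'   export rate).
#' @param delta_rms RMS amplitude of the delta component, uV.
#' @param delta_mod_depth Envelope modulation depth in `[0, 1]`: the delta
#'   amplitude follows `1 + depth * sin(2 pi f t)`.
#' @param delta_mod_freq Envelope frequency, Hz.
#' @param beta_rms RMS amplitude of the high-beta component, uV.
#' @param beta_burst_gain Multiplicative beta gain (>= 1) inside
#'   `burst_windows`.
#' @param burst_windows List of `c(start_s, end_s)` windows where the burst
#'   gain applies.
#' @param broadband_rms RMS of the pink (1/f) broadband floor, uV.
#' @param artifact_spikes List of `c(t_s, amplitude_uv)` brief (100 ms)
#'   triangular transients.
#' @param seed Integer seed; all draws flow from it.
#' @return List of class `eeg_gen_spec`.
#' @export
eeg_gen_spec <- function(duration_s = 300, fs = 128, delta_rms = 20,
                         delta_mod_depth = 0, delta_mod_freq = 1,
                         beta_rms = 5, beta_burst_gain = 1,
                         burst_windows = NULL, broadband_rms = 2,
                         artifact_spikes = NULL, seed = 1L) {
  stopifnot(duration_s > 0, fs >= 64,
            delta_rms >= 0, beta_rms >= 0, broadband_rms >= 0,
            delta_mod_depth >= 0, delta_mod_depth <= 1,
            beta_burst_gain >= 1)
  for (w in burst_windows)
    if (w[1] < 0 || w[2] <= w[1] || w[2] > duration_s)
      stop("burst window outside recording: [", w[1], ", ", w[2], "]")
  structure(list(duration_s = duration_s, fs = fs, delta_rms = delta_rms,
                 delta_mod_depth = delta_mod_depth,
                 delta_mod_freq = delta_mod_freq, beta_rms = beta_rms,
                 beta_burst_gain = beta_burst_gain,
                 burst_windows = burst_windows,
                 broadband_rms = broadband_rms,
                 artifact_spikes = artifact_spikes,
                 seed = as.integer(seed)),
            class = "eeg_gen_spec")
}

# Analytic-signal envelope via FFT, smoothed by a moving average; used to
# flatten a band-limited carrier's own amplitude fluctuations.
flatten_envelope <- function(x, fs, smooth_s = 0.5) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n); h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 } else h[2:((n + 1) / 2)] <- 2
  env <- Mod(fft(X * h, inverse = TRUE) / n)
  k <- max(1L, round(smooth_s * fs))
  sm <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- mean(env)
  sm <- pmax(sm, 0.1 * mean(env))
  x / sm
}

# Pink (1/f amplitude) noise via spectral shaping, unit RMS.
pink_noise <- function(n) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE) / n)
  x / sqrt(mean(x^2))
}

scale_rms <- function(x, rms) {
  r <- sqrt(mean(x^2))
  if (r == 0) return(x)
  x * (rms / r)
}

#' Generate a synthetic EEG recording
#'
#' Deterministic for a fixed spec (seed included): identical specs give
#' bit-identical recordings. The test window spans the whole recording.
#'
#' @param spec An [eeg_gen_spec()].
#' @return An [eeg_recording()].
#' @export
generate_eeg <- function(spec) {
  stopifnot(inherits(spec, "eeg_gen_spec"))
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  tt <- seq_len(n) / fs
  withr::with_seed(spec$seed, {
    x <- numeric(n)
    if (spec$delta_rms > 0) {
      carrier <- flatten_envelope(bandpass(rnorm(n), delta_band(), fs), fs)
      env <- 1 + spec$delta_mod_depth * sin(2 * pi * spec$delta_mod_freq * tt)
      x <- x + scale_rms(carrier, 1) * env * spec$delta_rms
    }
    if (spec$beta_rms > 0) {
      carrier <- flatten_envelope(bandpass(rnorm(n), high_beta_band(), fs), fs,
                                  smooth_s = 0.25)
      gain <- rep(1, n)
      for (w in spec$burst_windows) {
        i0 <- max(1L, round(w[1] * fs) + 1L); i1 <- min(n, round(w[2] * fs))
        gain[i0:i1] <- spec$beta_burst_gain
      }
      x <- x + scale_rms(carrier, 1) * gain * spec$beta_rms
    }
    if (spec$broadband_rms > 0)
      x <- x + pink_noise(n) * spec$broadband_rms
    for (sp in spec$artifact_spikes) {
      i0 <- round(sp[1] * fs) + 1L
      w <- max(3L, round(0.1 * fs))  # 100 ms triangular transient
      pulse <- sp[2] * (1 - abs(seq(-1, 1, length.out = w)))
      idx <- i0:(i0 + w - 1L)
      keep <- idx >= 1L & idx <= n
      x[idx[keep]] <- x[idx[keep]] + pulse[keep]
    }
    x
  }) -> samples
  eeg_recording(samples, fs, c(0, n / fs))
}
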