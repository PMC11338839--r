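test_that("cei_from_epoch_powers matches the direct SD/mean computation", {
  cfg <- cei_config()
  expect_equal(cei_from_epoch_powers(rep(3.7, 20), cfg)$value, 0)
  r <- cei_from_epoch_powers(c(rep(1, 10), rep(3, 10)), cfg)
  expect_identical(r$value, 0.5)   # mean 2, population SD 1, exactly
  expect_false(r$excluded)

  noisy <- c(rep(0.001, 19), 10)
  expect_gt(cei_oracle(noisy), 1)  # ratio ~ 4.35
  rn <- cei_from_epoch_powers(noisy, cfg)
  expect_true(rn$excluded)
  expect_equal(rn$reason, "noisy")

  flat <- cei_from_epoch_powers(rep(0, 20), cfg)
  expect_true(flat$excluded)
  expect_equal(flat$reason, "flat")

  expect_error(cei_from_epoch_powers(rep(1, 19), cfg), "20 epoch powers")
})

test_that("CEI is scale-invariant and increases with mean-preserving spread", {
  cfg <- cei_config()
  set.seed(31)
  for (i in 1:50) {
    p <- runif(20, 0.1, 2)
    v <- cei_from_epoch_powers(p, cfg)$value
    expect_equal(v, cei_oracle(p), tolerance = 1e-12)
    expect_equal(cei_from_epoch_powers(p * runif(1, 0.001, 1000), cfg)$value,
                 v, tolerance = 1e-12)
    # mean-preserving spread: move an epoch pair apart symmetrically
    q <- p
    eps <- 0.05 * min(p)
    i_lo <- which.min(q); i_hi <- which.max(q)
    q[i_lo] <- q[i_lo] - eps; q[i_hi] <- q[i_hi] + eps
    v2 <- cei_from_epoch_powers(q, cfg)$value
    if (!is.na(v2) && !is.na(v)) expect_gt(v2, v)
  }
})

test_that("unmodulated delta noise gives concentrated sub-middle CEI", {
  rec <- generate_eeg(eeg_gen_spec(duration_s = 300, delta_mod_depth = 0, seed = 41))
  s <- compute_cei_series(rec)
  expect_equal(nrow(s), 30L)
  expect_false(any(s$excluded))
  expect_true(all(s$cei < 0.5))
  expect_lt(IQR(s$cei), 0.15)
})

test_that("envelope modulation raises the CEI over the unmodulated carrier", {
  for (seed in c(51, 52, 53)) {
    flat_rec <- generate_eeg(eeg_gen_spec(120, delta_mod_depth = 0, seed = seed))
    mod_rec <- generate_eeg(eeg_gen_spec(120, delta_mod_depth = 0.9, seed = seed))
    expect_gt(median(compute_cei_series(mod_rec)$cei),
              median(compute_cei_series(flat_rec)$cei))
  }
})

test_that("CEI series is invariant to amplifier gain", {
  rec <- gated_recording(duration_s = 60, seed = 61)
  scaled <- eeg_recording(rec$samples * 1000, rec$fs, rec$test_window)
  expect_equal(compute_cei_series(scaled)$cei, compute_cei_series(rec)$cei,
               tolerance = 1e-6)
})

test_that("CEI of concatenated windows equals concatenated series", {
  a <- generate_eeg(eeg_gen_spec(50, delta_mod_depth = 0.5, seed = 71))
  b <- generate_eeg(eeg_gen_spec(40, delta_mod_depth = 0.5, seed = 72))
  joint <- eeg_recording(c(a$samples, b$samples), a$fs, c(0, 90))
  sj <- compute_cei_series(joint)
  expect_equal(sj$cei, c(compute_cei_series(a)$cei, compute_cei_series(b)$cei),
               tolerance = 1e-10)
})

test_that("percent_cei_middle counts valid points with closed bounds", {
  expect_equal(percent_cei_middle(c(0.1, 0.5, 0.6, 0.9)), 0.5)
  expect_equal(percent_cei_middle(rep(0.5, 7)), 1)
  expect_equal(percent_cei_middle(c(0.2, NA, 0.5)), 0.5)
  expect_equal(percent_cei_middle(c(1 / 3, 2 / 3, 0.9)), 2 / 3)  # inclusive
  open_cfg <- cei_config(middle_inclusive = FALSE)
  expect_equal(percent_cei_middle(c(1 / 3, 2 / 3, 0.5), open_cfg), 1 / 3)
  expect_warning(out <- percent_cei_middle(c(NA_real_, NA_real_)), "missing")
  expect_true(is.na(out))
})

test_that("causal FIR filtering stays close to the zero-phase reference", {
  rec <- generate_eeg(eeg_gen_spec(300, delta_mod_depth = 0.9, seed = 17))
  zp <- compute_cei_series(rec)
  fir <- compute_cei_series(rec, cei_config(filter = "fir"))
  d <- abs(zp$cei - fir$cei)
  # the ~0.5 s group delay shifts epoch boundaries; the index stays close
  expect_lt(median(d, na.rm = TRUE), 0.1)
  expect_lt(max(d, na.rm = TRUE), 0.2)
  expect_equal(percent_cei_middle(fir), percent_cei_middle(zp),
               tolerance = 0.1)
  # and the causal filter still rejects out-of-band tones
  t <- seq_len(10 * 128) / 128
  y <- bandpass(sin(2 * pi * 26 * t), delta_band(), 128, method = "fir")
  expect_lt(sqrt(mean(y[200:1000]^2)) / sqrt(0.5), 0.01)
})

test_that("artifact spikes drive segments into exclusion", {
  spikes <- list(c(13, 4000), c(16, 4000))
  rec <- generate_eeg(eeg_gen_spec(60, delta_mod_depth = 0, seed = 81,
                                   artifact_spikes = spikes))
  s <- compute_cei_series(rec)
  expect_true(s$excluded[2])   # the spiked segment (10-20 s)
  expect_false(any(s$excluded[-2]))
})
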