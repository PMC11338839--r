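test_that("tensi_value implements the halved, clamped baseline ratio", {
  expect_identical(tensi_value(4, 4), 0.5)
  expect_identical(tensi_value(12, 4), 1)     # 3x baseline clamps
  expect_identical(tensi_value(8, 4), 1)      # exactly 2x hits the clamp
  expect_identical(tensi_value(0, 4), 0)
  expect_true(is.na(tensi_value(4, NA)))
  expect_true(is.na(tensi_value(4, 0)))
  # monotone nondecreasing in segment power
  p <- seq(0, 20, by = 0.5)
  v <- vapply(p, tensi_value, numeric(1), baseline_mean = 4)
  expect_true(all(diff(v) >= 0))
})

test_that("the running baseline matches the hand-simulated example", {
  v <- cogmark:::tensi_points_from_powers(c(4, 4, 8, 4), rep(TRUE, 4))$tensi
  expect_identical(v[1], NA_real_)
  expect_identical(v[2], 0.5)
  expect_identical(v[3], 1)           # baseline (4+4)/2 = 4, ratio 2 clamps
  expect_identical(v[4], 0.375)       # baseline (4+4+8)/3, 4/(16/3)/2
})

test_that("constant gated power gives 0.5 everywhere; closed gate gives NA", {
  v <- cogmark:::tensi_points_from_powers(rep(6, 10), rep(TRUE, 10))$tensi
  expect_equal(v, c(NA, rep(0.5, 9)))
  v2 <- cogmark:::tensi_points_from_powers(rep(6, 10), rep(FALSE, 10))$tensi
  expect_true(all(is.na(v2)))
})

test_that("a segment's own power never enters its own baseline", {
  # second segment doubles the power; if it leaked into its own baseline the
  # value would be (8 / mean(4,8)) / 2 = 2/3, not 1
  v <- cogmark:::tensi_points_from_powers(c(4, 8), c(TRUE, TRUE))$tensi
  expect_identical(v[2], 1)
})

test_that("percent_tensi_high uses a strict threshold over defined points", {
  expect_equal(percent_tensi_high(c(0.5, 0.7, 1.0, NA)), 2 / 3)
  expect_equal(percent_tensi_high(rep(0.5, 5)), 0)
  expect_equal(percent_tensi_high(2 / 3), 0)   # strict inequality
  expect_warning(out <- percent_tensi_high(NA_real_), "missing")
  expect_true(is.na(out))
})

test_that("streaming and batch TensI are bit-identical on synthetic EEG", {
  for (seed in c(91, 92)) {
    rec <- generate_eeg(eeg_gen_spec(200, delta_mod_depth = 0.9, seed = seed,
                                     beta_burst_gain = 3,
                                     burst_windows = list(c(100, 130))))
    batch <- compute_tensi_series(rec)
    strm <- compute_tensi_series(rec, stream = TRUE)
    expect_identical(strm$tensi, batch$tensi)
    expect_identical(strm$baseline_n, batch$baseline_n)
    expect_identical(strm$baseline_mean, batch$baseline_mean)
  }
})

test_that("TensI is invariant to amplifier gain", {
  rec <- gated_recording(duration_s = 80, seed = 101)
  scaled <- eeg_recording(rec$samples * 250, rec$fs, rec$test_window)
  expect_equal(compute_tensi_series(scaled)$tensi,
               compute_tensi_series(rec)$tensi, tolerance = 1e-6)
})

test_that("stationary gated beta converges to TensI 0.5", {
  rec <- gated_recording(duration_s = 320, seed = 111)
  s <- compute_tensi_series(rec)
  expect_gte(sum(s$defined), 30)
  expect_lt(max(abs(s$tensi[s$defined] - 0.5)), 0.05)
})

test_that("a 4x beta burst saturates TensI and raises the high fraction", {
  base <- eeg_gen_spec(300, delta_mod_depth = 0.9, seed = 121)
  burst <- eeg_gen_spec(300, delta_mod_depth = 0.9, seed = 121,
                        beta_burst_gain = 4,
                        burst_windows = list(c(100, 150)))  # segments 10-14
  s0 <- compute_tensi_series(generate_eeg(base))
  s1 <- compute_tensi_series(generate_eeg(burst))
  expect_gt(percent_tensi_high(s1), percent_tensi_high(s0))
  in_burst <- s1$segment %in% 10:14 & s1$defined
  expect_true(all(s1$tensi[in_burst] > 0.95))
})

test_that("noisy segments get TensI but never extend the baseline", {
  spikes <- list(c(33, 4000), c(36, 4000))
  rec <- generate_eeg(eeg_gen_spec(80, delta_mod_depth = 0.9, seed = 131,
                                   artifact_spikes = spikes))
  cei <- compute_cei_series(rec)
  expect_true(cei$excluded[4])
  s <- compute_tensi_series(rec, cei)
  expect_true(s$defined[4])                      # still valued
  expect_equal(s$baseline_n[5], s$baseline_n[4]) # but not in the baseline
  strict <- compute_tensi_series(rec, cei, tensi_config(skip_noisy = TRUE))
  expect_false(strict$defined[4])
})

test_that("a gate that never opens leaves every point undefined", {
  rec <- generate_eeg(eeg_gen_spec(60, delta_mod_depth = 0, seed = 141))
  cei <- compute_cei_series(rec)
  expect_true(all(cei$cei < 1 / 3))  # unmodulated carrier sits low
  expect_warning(s <- compute_tensi_series(rec, cei), "no baseline")
  expect_true(all(!s$defined))
  expect_warning(out <- percent_tensi_high(s), "missing")
  expect_true(is.na(out))
})
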