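# Shared fixtures and independent oracles.

# Short stationary recording with middle-third CEI (deep envelope modulation
# keeps segments baseline-gated).
gated_recording <- function(duration_s = 120, seed = 11, ...) {
  generate_eeg(eeg_gen_spec(duration_s = duration_s, delta_mod_depth = 0.9,
                            seed = seed, ...))
}

# Two-pass population-SD/mean oracle for the CEI, via stats::sd.
cei_oracle <- function(powers) {
  n <- length(powers)
  stats::sd(powers) * sqrt((n - 1) / n) / mean(powers)
}

# Brute-force Mann-Whitney: enumerate every assignment of the pooled ranks
# to group A, two-sided p as the fraction of assignments at least as far
# from the null mean U as observed.
mw_brute_force_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); nb <- length(b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  m <- na * nb / 2
  cmb <- utils::combn(na + nb, na)
  us <- apply(cmb, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mean(abs(us - m) >= abs(u_obs - m) - 1e-9)
}

# Closed-form 2x2 chi-square statistic (no continuity correction).
chisq_2x2_formula <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  (a * d - b * c_)^2 * n / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# Minimal valid cohort row(s) for schema-level tests.
tiny_cohort <- function(pre, post, seed = 1) {
  cells <- data.frame(range = as.character(classify_range(pre)),
                      delta = post - pre, n = 1L)
  # exact totals matter for some tests: build directly
  n <- length(pre)
  coh <- generate_cohort(cohort_gen_spec(
    cells = data.frame(range = "intermediate", delta = 0, n = n), seed = seed))
  coh$moca_pre_total <- pre
  coh$moca_post_total <- post
  # keep subscores consistent enough for validation (totals only are used)
  for (s in names(moca_subscore_max)) {
    coh[[paste0("moca_pre_", s)]] <- NA_integer_
    coh[[paste0("moca_post_", s)]] <- NA_integer_
  }
  coh
}
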