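test_that("Mann-Whitney matches hand-checked exact cases", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)            # 2/20 rank assignments as extreme
  expect_true(r$suppressed)         # n < 5 both sides
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney agrees with brute-force enumeration for all n_a + n_b <= 10", {
  set.seed(161)
  for (na in 1:9) for (nb in 1:(10 - na)) {
    vals <- sample(seq(0.01, 0.99, length.out = 40), na + nb)  # distinct
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(mann_whitney(a, b)$p, mw_brute_force_p(a, b),
                 tolerance = 1e-12,
                 info = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(171)
  a <- runif(12); b <- runif(15)
  p0 <- mann_whitney(a, b)$p
  expect_equal(mann_whitney(exp(5 * a), exp(5 * b))$p, p0)
  expect_equal(mann_whitney(qnorm(a), qnorm(b))$p, p0)
})

test_that("t comparisons: paired identity, separation, and symmetry", {
  x <- c(3, 5, 7, 9)
  r <- t_compare(x, x, paired = TRUE)
  expect_equal(r$statistic, 0); expect_equal(r$p, 1)

  set.seed(181)
  a <- rnorm(4, 0, 1e-6); b <- 1 + rnorm(4, 0, 1e-6)
  expect_lt(t_compare(a, b)$p, 1e-6)

  c1 <- rnorm(10); c2 <- rnorm(12, 0.5)
  r12 <- t_compare(c1, c2); r21 <- t_compare(c2, c1)
  expect_equal(r12$p, r21$p)
  expect_equal(r12$statistic, -r21$statistic)
  expect_error(t_compare(1, 1:5), "n >= 2")
})

test_that("quadrant analysis separates constructed groups and flags small n", {
  dec <- data.frame(x = runif(8, 0.7, 0.95), y = runif(8, 0.7, 0.95))
  inc <- data.frame(x = runif(8, 0.05, 0.3), y = runif(8, 0.05, 0.3))
  q <- quadrant_analysis(inc, dec)
  expect_equal(q$frac_decrease, 1)
  expect_equal(q$frac_increase, 0)
  expect_lt(q$p_value, 0.05)
  expect_equal(q$statistic, chisq_2x2_formula(q$counts))

  pts <- data.frame(x = runif(10), y = runif(10))
  q2 <- quadrant_analysis(pts, pts)
  expect_equal(q2$frac_increase, q2$frac_decrease)
  expect_equal(q2$statistic, 0, tolerance = 1e-12)

  expect_warning(
    q3 <- quadrant_analysis(data.frame(x = 0.2, y = 0.2),
                            data.frame(x = 0.8, y = 0.8)),
    "expected cell")
  expect_true(q3$suppressed)
})

test_that("quadrant membership is strict: points on a median are outside", {
  inc <- data.frame(x = c(0.4, 0.6), y = c(0.4, 0.6))
  dec <- data.frame(x = c(0.5, 0.7), y = c(0.5, 0.7))
  q <- quadrant_analysis(inc, dec)
  # pooled medians are 0.55; only points strictly above both count
  expect_equal(q$counts["in_quadrant", "increase"], 1)
  expect_equal(q$counts["in_quadrant", "decrease"], 1)
})

test_that("chi-square statistic equals the closed-form 2x2 formula", {
  set.seed(191)
  for (i in 1:20) {
    tab <- matrix(sample(5:40, 4), 2)
    expect_equal(unname(suppressWarnings(
      chisq.test(tab, correct = FALSE)$statistic)),
      chisq_2x2_formula(tab), tolerance = 1e-12)
  }
})

test_that("stratified report covers strata, suppresses small groups", {
  cells <- rbind(
    data.frame(range = "intermediate", delta = c(-2, 2), n = c(20, 30)),
    data.frame(range = "lower", delta = c(-1, 1), n = c(4, 10)))
  coh <- generate_cohort(cohort_gen_spec(cells = cells, seed = 201))
  rep <- run_stratified_comparisons(coh)
  cmp <- rep$comparisons
  expect_true(all(cmp$stratum %in% moca_ranges))
  expect_false("higher" %in% cmp$stratum)   # no patients there, no crash
  low1 <- cmp[cmp$stratum == "lower" & cmp$threshold == 1 &
                cmp$variable == "pcei_m_pre", ]
  expect_true(low1$suppressed)              # 4 decrease patients
  int1 <- cmp[cmp$stratum == "intermediate" & cmp$threshold == 1 &
                cmp$variable == "pcei_m_pre", ]
  expect_false(int1$suppressed)
  expect_true(all(cmp$p >= 0 & cmp$p <= 1, na.rm = TRUE))
  # thresholds flag restricts the blocks emitted
  rep2 <- run_stratified_comparisons(coh, thresholds = 2)
  expect_equal(unique(rep2$comparisons$threshold), 2)
})

test_that("an injected marker shift is detected in the stratified report", {
  cells <- data.frame(range = "intermediate", delta = c(-1, 1), n = c(20, 45))
  hits <- 0L
  for (seed in 1:25) {
    coh <- generate_cohort(cohort_gen_spec(
      cells = cells, pcei_pre_shift_decrease = 0.25, seed = 300 + seed))
    rep <- run_stratified_comparisons(coh, thresholds = 1)
    p <- rep$comparisons$p[rep$comparisons$stratum == "intermediate" &
                             rep$comparisons$variable == "pcei_m_pre"]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 20L)   # >= 80% of replicates
})

test_that("report writer produces a tidy TSV and a JSON mirror", {
  coh <- reference_cohort(seed = 8)
  rep <- run_stratified_comparisons(coh, thresholds = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_comparison_report(rep, tsv, js)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(rep$comparisons))
  expect_true(all(c("stratum", "threshold", "variable", "test", "p",
                    "suppressed") %in% names(back)))
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$table1$n_total, 117)
})
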