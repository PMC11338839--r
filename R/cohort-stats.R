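# Group-comparison machinery over stratified cohorts: Mann-Whitney for the
# non-normal marker summaries, Welch/paired t for age, HADS and subscores,
# and the median-split quadrant chi-square. Groups with fewer than five
# patients are flagged suppressed (mirrors the display rule applied to the
# marker figures).

comparison_result <- function(test_name, statistic, p_value, n_a, n_b,
                              center_a, center_b, spread_a, spread_b,
                              min_n = 5L) {
  data.frame(test = test_name, statistic = statistic, p = p_value,
             n_a = n_a, n_b = n_b,
             center_a = center_a, center_b = center_b,
             spread_a = spread_a, spread_b = spread_b,
             suppressed = (n_a < min_n | n_b < min_n),
             stringsAsFactors = FALSE)
}

#' Two-sided Mann-Whitney U comparison
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. Reports medians and IQRs per group. Rank-based,
#' hence invariant under any strictly monotone transform of the values.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param min_n Groups smaller than this are flagged suppressed (default 5).
#' @return One-row data.frame (`ComparisonResult`): test, U statistic, p,
#'   group sizes, medians (`center_*`), IQRs (`spread_*`), `suppressed`.
#' @export
mann_whitney <- function(values_a, values_b, min_n = 5L) {
  values_a <- values_a[!is.na(values_a)]; values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- (length(values_a) + length(values_b) <= 20L) && !ties
  w <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  comparison_result("mann_whitney", unname(w$statistic), w$p.value,
                    length(values_a), length(values_b),
                    median(values_a), median(values_b),
                    IQR(values_a), IQR(values_b), min_n)
}

#' Two-sided t comparison (Welch unpaired or paired)
#'
#' Unpaired comparisons use the Welch correction by default (pooled
#' variance available via `var_equal = TRUE`). Degenerate zero-variance
#' inputs with equal means give t = 0, p = 1.
#'
#' @param values_a,values_b Numeric vectors; for `paired = TRUE`,
#'   equal-length aligned vectors (NA pairs dropped).
#' @param paired Paired comparison (pre vs post within patient).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param min_n Suppression threshold (default 5).
#' @return One-row `ComparisonResult` with means (`center_*`) and SDs
#'   (`spread_*`).
#' @export
t_compare <- function(values_a, values_b, paired = FALSE, var_equal = FALSE,
                      min_n = 5L) {
  if (paired) {
    if (length(values_a) != length(values_b))
      stop("paired comparison needs aligned vectors of equal length")
    ok <- !is.na(values_a) & !is.na(values_b)
    values_a <- values_a[ok]; values_b <- values_b[ok]
    if (length(values_a) < 2L) stop("paired comparison needs n >= 2")
  } else {
    values_a <- values_a[!is.na(values_a)]; values_b <- values_b[!is.na(values_b)]
    if (length(values_a) < 2L || length(values_b) < 2L)
      stop("unpaired comparison needs n >= 2 per group")
  }
  degenerate <- if (paired) sd(values_a - values_b) == 0 else
    sd(values_a) == 0 && sd(values_b) == 0
  if (degenerate) {  # constant data: t.test is undefined (0/0) or errors
    delta <- if (paired) mean(values_a - values_b) else mean(values_a) - mean(values_b)
    if (abs(delta) < .Machine$double.eps^0.5) {
      stat <- 0; p <- 1
    } else {
      stat <- sign(delta) * Inf; p <- 0
    }
  } else {
    res <- stats::t.test(values_a, values_b, paired = paired,
                         var.equal = var_equal)
    stat <- unname(res$statistic); p <- res$p.value
  }
  comparison_result(if (paired) "t_paired" else if (var_equal) "t_pooled" else "t_welch",
                    stat, p, length(values_a), length(values_b),
                    mean(values_a), mean(values_b),
                    sd(values_a), sd(values_b), min_n)
}

#' Median-split quadrant analysis
#'
#' Each patient is a point (preoperative `%CEIm`, postoperative
#' `%TensI-high`). The x and y medians are computed over the POOLED groups;
#' a point is in the upper-right quadrant iff strictly above both medians.
#' Group membership vs quadrant occupancy is compared with a 1-df 2x2
#' chi-square (no continuity correction, matching the closed-form
#' `(ad-bc)^2 N / (row x col products)` statistic); Fisher's exact test is
#' available for small tables.
#'
#' @param points_increase,points_decrease Data.frames (or 2-col matrices)
#'   with columns `x`, `y`; one row per patient.
#' @param exact Use Fisher's exact test instead of the chi-square.
#' @param min_n Suppression threshold per group (default 5).
#' @return List of class `quadrant_result`: `median_x`, `median_y`,
#'   `frac_increase`, `frac_decrease` (upper-right occupancy per group),
#'   `counts` (2x2), `statistic`, `p_value`, `suppressed`, `small_sample`
#'   (TRUE when any expected cell < 1).
#' @export
quadrant_analysis <- function(points_increase, points_decrease,
                              exact = FALSE, min_n = 5L) {
  as_pts <- function(p) {
    p <- as.data.frame(p)
    if (!all(c("x", "y") %in% names(p))) names(p)[1:2] <- c("x", "y")
    p[stats::complete.cases(p[, c("x", "y")]), c("x", "y")]
  }
  inc <- as_pts(points_increase); dec <- as_pts(points_decrease)
  n_i <- nrow(inc); n_d <- nrow(dec)
  if (n_i + n_d < 2L) stop("need at least 2 pooled points")
  mx <- median(c(inc$x, dec$x)); my <- median(c(inc$y, dec$y))
  in_q <- function(p) p$x > mx & p$y > my
  qi <- sum(in_q(inc)); qd <- sum(in_q(dec))
  counts <- matrix(c(qd, n_d - qd, qi, n_i - qi), nrow = 2,
                   dimnames = list(c("in_quadrant", "out"),
                                   c("decrease", "increase")))
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  small <- any(expected < 1)
  if (small)
    warning("expected cell count < 1; chi-square approximation unreliable")
  if (exact) {
    ft <- stats::fisher.test(counts)
    stat <- NA_real_; p <- ft$p.value
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value
    if (is.nan(p)) { stat <- 0; p <- 1 }  # degenerate margin
  }
  structure(list(median_x = mx, median_y = my,
                 frac_increase = if (n_i) qi / n_i else NA_real_,
                 frac_decrease = if (n_d) qd / n_d else NA_real_,
                 counts = counts, statistic = stat, p_value = p,
                 n_increase = n_i, n_decrease = n_d,
                 suppressed = (n_i < min_n | n_d < min_n),
                 small_sample = small),
            class = "quadrant_result")
}

#' @export
print.quadrant_result <- function(x, ...) {
  cat(sprintf(
    "<quadrant_result> medians x=%.3f y=%.3f | upper-right: decrease %.0f%% (n=%d), increase %.0f%% (n=%d) | chi-sq=%s p=%.4g%s\n",
    x$median_x, x$median_y, 100 * x$frac_decrease, x$n_decrease,
    100 * x$frac_increase, x$n_increase,
    if (is.na(x$statistic)) "NA" else sprintf("%.3f", x$statistic),
    x$p_value, if (x$suppressed) " [suppressed: n < 5]" else ""))
  invisible(x)
}

#' Stratified decrease-vs-increase comparison report
#'
#' For every preoperative MoCA range and change threshold in 1/2/3: (a)
#' Mann-Whitney comparisons of the marker summaries between the decrease
#' and increase groups (pre, post, and intrapatient delta, for `%CEIm` and
#' `%TensI-high`), and of pre vs post within each group; (b) Welch t-tests
#' for age and the six HADS scores between groups; (c) paired t-tests for
#' each of the seven MoCA subscores, pre vs post, within each group; (d)
#' the quadrant analysis (pre `%CEIm` x post `%TensI-high`). Comparisons
#' involving a group below `min_n` are flagged suppressed.
#'
#' @param cohort Validated cohort data.frame (see [cohort_schema()]).
#' @param thresholds Change thresholds to analyze (subset of 1:3).
#' @param min_n Suppression threshold (default 5).
#' @param paired_markers If TRUE, the within-group pre-vs-post marker
#'   comparisons use the paired Wilcoxon signed-rank test instead of the
#'   unpaired Mann-Whitney (divergence option; default FALSE).
#' @return List of class `cogmark_report`: `comparisons` (tidy data.frame:
#'   stratum, threshold, variable, test, statistic, p, n_a, n_b, centers,
#'   spreads, suppressed), `quadrants` (named list of `quadrant_result`),
#'   `table1` (the [table1_counts()] bookkeeping).
#' @export
run_stratified_comparisons <- function(cohort, thresholds = 1:3, min_n = 5L,
                                       paired_markers = FALSE) {
  cohort <- validate_cohort(cohort)
  ok <- stats::complete.cases(cohort[, c("moca_pre_total", "moca_post_total")])
  cohort <- cohort[ok, ]
  rng <- classify_range(cohort$moca_pre_total)
  rows <- list(); quads <- list()

  add <- function(stratum, thr, variable, res) {
    res$stratum <- stratum; res$threshold <- thr; res$variable <- variable
    rows[[length(rows) + 1L]] <<- res
  }
  mw_or_na <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) return(NULL)
    mann_whitney(a, b, min_n)
  }
  within_group_prepost <- function(pre, post) {
    ok <- !is.na(pre) & !is.na(post)
    if (paired_markers) {
      if (sum(ok) < 2L) return(NULL)
      w <- suppressWarnings(stats::wilcox.test(pre[ok], post[ok], paired = TRUE))
      comparison_result("wilcoxon_paired", unname(w$statistic), w$p.value,
                        sum(ok), sum(ok), median(pre[ok]), median(post[ok]),
                        IQR(pre[ok]), IQR(post[ok]), min_n)
    } else {
      mw_or_na(pre, post)
    }
  }

  for (r in moca_ranges) for (thr in thresholds) {
    cc <- change_category(cohort$moca_pre_total, cohort$moca_post_total, thr)
    dec <- cohort[rng == r & cc == "decrease", ]
    inc <- cohort[rng == r & cc == "increase", ]
    key <- paste0(r, "_ge", thr)
    if (nrow(dec) == 0L && nrow(inc) == 0L) next

    if (nrow(dec) > 0L && nrow(inc) > 0L) {
      marker_vars <- list(
        pcei_m_pre = c("pcei_m_pre"), pcei_m_post = c("pcei_m_post"),
        ptensi_hi_pre = c("ptensi_hi_pre"), ptensi_hi_post = c("ptensi_hi_post"))
      for (v in names(marker_vars)) {
        res <- mw_or_na(dec[[v]], inc[[v]])
        if (!is.null(res)) add(r, thr, v, res)
      }
      res <- mw_or_na(dec$pcei_m_post - dec$pcei_m_pre,
                      inc$pcei_m_post - inc$pcei_m_pre)
      if (!is.null(res)) add(r, thr, "delta_pcei_m", res)
      res <- mw_or_na(dec$ptensi_hi_post - dec$ptensi_hi_pre,
                      inc$ptensi_hi_post - inc$ptensi_hi_pre)
      if (!is.null(res)) add(r, thr, "delta_ptensi_hi", res)

      tvars <- c("age", "hads_pre_total", "hads_pre_anx", "hads_pre_dep",
                 "hads_post_total", "hads_post_anx", "hads_post_dep")
      for (v in tvars) {
        a <- dec[[v]][!is.na(dec[[v]])]; b <- inc[[v]][!is.na(inc[[v]])]
        if (length(a) >= 2L && length(b) >= 2L)
          add(r, thr, v, t_compare(a, b, min_n = min_n))
      }
    }
    grp_list <- list(decrease = dec, increase = inc)
    for (gname in names(grp_list)) {
      g <- grp_list[[gname]]
      if (nrow(g) == 0L) next
      res <- within_group_prepost(g$pcei_m_pre, g$pcei_m_post)
      if (!is.null(res)) add(r, thr, paste0("pcei_m_pre_vs_post_", gname), res)
      res <- within_group_prepost(g$ptensi_hi_pre, g$ptensi_hi_post)
      if (!is.null(res)) add(r, thr, paste0("ptensi_hi_pre_vs_post_", gname), res)
      for (s in names(moca_subscore_max)) {
        pre <- g[[paste0("moca_pre_", s)]]; post <- g[[paste0("moca_post_", s)]]
        okp <- !is.na(pre) & !is.na(post)
        if (sum(okp) >= 2L)
          add(r, thr, paste0("subscore_", s, "_", gname),
              t_compare(pre[okp], post[okp], paired = TRUE, min_n = min_n))
      }
    }
    if (nrow(dec) > 0L && nrow(inc) > 0L && nrow(dec) + nrow(inc) >= 2L) {
      quads[[key]] <- suppressWarnings(quadrant_analysis(
        data.frame(x = inc$pcei_m_pre, y = inc$ptensi_hi_post),
        data.frame(x = dec$pcei_m_pre, y = dec$ptensi_hi_post),
        min_n = min_n))
    }
  }

  if (length(rows)) {
    comparisons <- do.call(rbind, rows)
  } else {
    comparisons <- comparison_result("none", NA, NA, 0L, 0L, NA, NA, NA, NA)[0, ]
    comparisons$stratum <- character(0)
    comparisons$threshold <- integer(0)
    comparisons$variable <- character(0)
  }
  front <- c("stratum", "threshold", "variable")
  comparisons <- comparisons[, c(front, setdiff(names(comparisons), front))]
  rownames(comparisons) <- NULL
  structure(list(comparisons = comparisons, quadrants = quads,
                 table1 = table1_counts(cohort)),
            class = "cogmark_report")
}

#' @export
print.cogmark_report <- function(x, ...) {
  cat("<cogmark_report>", nrow(x$comparisons), "comparisons,",
      length(x$quadrants), "quadrant analyses,",
      x$table1$n_total, "patients (", x$table1$n_analysis, "with change )\n")
  sig <- x$comparisons[!x$comparisons$suppressed & x$comparisons$p < 0.05, ]
  if (nrow(sig)) {
    cat("significant (p < 0.05, unsuppressed):\n")
    print(sig[, c("stratum", "threshold", "variable", "test", "p")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a comparison report as tidy TSV + JSON
#'
#' @param report A `cogmark_report`.
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @param provenance Optional provenance block to embed in the JSON.
#' @return Invisibly, the report.
#' @export
write_comparison_report <- function(report, tsv_path = NULL, json_path = NULL,
                                    provenance = NULL) {
  stopifnot(inherits(report, "cogmark_report"))
  if (!is.null(tsv_path))
    utils::write.table(report$comparisons, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    quads <- lapply(report$quadrants, function(q)
      q[c("median_x", "median_y", "frac_increase", "frac_decrease",
          "statistic", "p_value", "n_increase", "n_decrease", "suppressed")])
    payload <- list(comparisons = report$comparisons, quadrants = quads,
                    table1 = list(counts = report$table1$counts,
                                  percent_of_all = report$table1$percent_of_all,
                                  n_total = report$table1$n_total,
                                  n_no_change = report$table1$n_no_change,
                                  n_analysis = report$table1$n_analysis))
    if (!is.null(provenance)) payload$provenance <- provenance
    jsonlite::write_json(payload, json_path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
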