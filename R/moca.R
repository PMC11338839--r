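# MoCA data model: 0-30 total, seven subscores, a-priori range partition of
# the preoperative total, change categorization at 1/2/3-point thresholds,
# and the range-by-threshold bookkeeping table.

#' Maximum points per MoCA subscore (standard form)
#' @export
moca_subscore_max <- c(executive_visuospatial = 5L, naming = 3L, attention = 6L,
                       language = 3L, abstraction = 2L, memory = 5L,
                       orientation = 6L)

#' Names of the three preoperative MoCA ranges
#' @export
moca_ranges <- c("lower", "intermediate", "higher")

#' One MoCA sitting: total and seven subscores
#'
#' @param total Integer 0-30.
#' @param subscores Named integer vector with the seven subscores
#'   (`executive_visuospatial`, `naming`, `attention`, `language`,
#'   `abstraction`, `memory`, `orientation`), each within its maximum.
#'   Optional; when given, must sum to `total`.
#' @return List of class `moca_assessment`.
#' @export
moca_assessment <- function(total, subscores = NULL) {
  total <- as.integer(total)
  if (is.na(total) || total < 0L || total > 30L)
    stop("MoCA total must be an integer in 0..30")
  if (!is.null(subscores)) {
    if (!setequal(names(subscores), names(moca_subscore_max)))
      stop("subscores must be named: ",
           paste(names(moca_subscore_max), collapse = ", "))
    subscores <- subscores[names(moca_subscore_max)]
    bad <- subscores < 0L | subscores > moca_subscore_max
    if (any(bad)) stop("subscore out of range: ",
                       paste(names(subscores)[bad], collapse = ", "))
    if (sum(subscores) != total)
      stop("subscores sum to ", sum(subscores), ", not the total ", total)
  }
  structure(list(total = total, subscores = subscores),
            class = "moca_assessment")
}

#' Preoperative MoCA range
#'
#' The a-priori partition: lower (<= 20, in all likelihood abnormal),
#' intermediate (21-25), higher (>= 26, in high likelihood normal).
#'
#' @param pre_total Integer MoCA total(s), 0-30 (vectorized).
#' @return Factor with levels `lower`, `intermediate`, `higher`.
#' @export
classify_range <- function(pre_total) {
  pre_total <- as.integer(pre_total)
  if (any(is.na(pre_total) | pre_total < 0L | pre_total > 30L))
    stop("MoCA total must be in 0..30")
  factor(ifelse(pre_total <= 20L, "lower",
                ifelse(pre_total <= 25L, "intermediate", "higher")),
         levels = moca_ranges)
}

#' Perioperative change category at a point threshold
#'
#' `decrease` iff `pre - post >= threshold`; `increase` iff
#' `post - pre >= threshold`; otherwise `neither`. Categories nest: a
#' decrease at threshold 3 is also a decrease at thresholds 2 and 1.
#'
#' @param pre_total,post_total Integer totals (vectorized).
#' @param threshold Points threshold, one of 1, 2, 3.
#' @return Factor with levels `decrease`, `neither`, `increase`.
#' @export
change_category <- function(pre_total, post_total, threshold = 1L) {
  if (!threshold %in% 1:3) stop("threshold must be 1, 2 or 3")
  d <- as.integer(post_total) - as.integer(pre_total)
  factor(ifelse(d <= -threshold, "decrease",
                ifelse(d >= threshold, "increase", "neither")),
         levels = c("decrease", "neither", "increase"))
}

round_half_up <- function(x) floor(x + 0.5)

#' Range-by-threshold bookkeeping of perioperative MoCA change
#'
#' Counts, per preoperative range and overall, the patients with a decrease
#' of at least 3/2/1 points, no change, and an increase of at least 1/2/3
#' points (the threshold columns nest), plus an integer percent-of-all row
#' (round half up). Patients lacking a pre or post total are excluded with
#' a warning.
#'
#' @param cohort Cohort data.frame with `moca_pre_total`, `moca_post_total`
#'   (see [cohort_schema()]).
#' @return List: `counts` (4 x 7 integer matrix, rows lower/intermediate/
#'   higher/Total; columns dec_ge3..inc_ge3), `percent_of_all` (integer
#'   percents of the Total row), `n_total`, `n_no_change`, `n_analysis`
#'   (patients with any change, the comparison set).
#' @export
table1_counts <- function(cohort) {
  need <- c("moca_pre_total", "moca_post_total")
  if (!all(need %in% names(cohort))) stop("cohort lacks MoCA total columns")
  ok <- stats::complete.cases(cohort[, need])
  if (any(!ok)) {
    warning(sum(!ok), " patient(s) missing a pre or post MoCA total; excluded")
    cohort <- cohort[ok, ]
  }
  pre <- as.integer(cohort$moca_pre_total)
  post <- as.integer(cohort$moca_post_total)
  rng <- classify_range(pre)
  d <- post - pre
  cols <- c("dec_ge3", "dec_ge2", "dec_ge1", "no_change",
            "inc_ge1", "inc_ge2", "inc_ge3")
  count_row <- function(sel) {
    dd <- d[sel]
    as.integer(c(sum(dd <= -3), sum(dd <= -2), sum(dd <= -1), sum(dd == 0),
                 sum(dd >= 1), sum(dd >= 2), sum(dd >= 3)))
  }
  counts <- rbind(lower = count_row(rng == "lower"),
                  intermediate = count_row(rng == "intermediate"),
                  higher = count_row(rng == "higher"),
                  Total = count_row(rep(TRUE, length(d))))
  colnames(counts) <- cols
  n <- length(d)
  pct <- round_half_up(counts["Total", ] / n * 100)
  list(counts = counts, percent_of_all = pct,
       n_total = n, n_no_change = unname(counts["Total", "no_change"]),
       n_analysis = n - unname(counts["Total", "no_change"]))
}

#' Cohort CSV schema
#'
#' Column names of the per-patient cohort table: id, demographics, pre/post
#' MoCA totals and seven subscores, pre/post HADS (total, anxiety,
#' depression), and the per-test marker summaries (`%CEIm`, `%TensI-high`
#' as fractions in `[0, 1]`). Missing values are empty cells.
#'
#' @return Character vector of required column names.
#' @export
cohort_schema <- function() {
  sub <- names(moca_subscore_max)
  c("id", "age", "sex", "moca_pre_total", "moca_post_total",
    paste0("moca_pre_", sub), paste0("moca_post_", sub),
    "hads_pre_total", "hads_pre_anx", "hads_pre_dep",
    "hads_post_total", "hads_post_anx", "hads_post_dep",
    "pcei_m_pre", "pcei_m_post", "ptensi_hi_pre", "ptensi_hi_post")
}

validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_schema(), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  chk_rng <- function(col, lo, hi) {
    v <- cohort[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad)) stop("column ", col, " out of range [", lo, ",", hi,
                          "] at rows: ", paste(head(bad, 5), collapse = ", "))
  }
  chk_rng("moca_pre_total", 0, 30); chk_rng("moca_post_total", 0, 30)
  for (s in names(moca_subscore_max)) {
    chk_rng(paste0("moca_pre_", s), 0, moca_subscore_max[[s]])
    chk_rng(paste0("moca_post_", s), 0, moca_subscore_max[[s]])
  }
  for (col in c("hads_pre_anx", "hads_pre_dep", "hads_post_anx", "hads_post_dep"))
    chk_rng(col, 0, 21)
  for (col in c("hads_pre_total", "hads_post_total")) chk_rng(col, 0, 42)
  for (col in c("pcei_m_pre", "pcei_m_post", "ptensi_hi_pre", "ptensi_hi_post"))
    chk_rng(col, 0, 1)
  invisible(cohort)
}

#' Read and validate a cohort CSV
#' @param path CSV path with the [cohort_schema()] columns.
#' @return Validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}
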