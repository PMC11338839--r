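# Seeded per-patient cohort generator: exact cell counts per (preoperative
# MoCA range x perioperative change), subscores that sum to the totals,
# truncated-normal marker summaries with controllable decrease-vs-increase
# group effects, HADS and age draws.

#' Reference perioperative cohort composition
#'
#' Nested change-threshold counts for a 117-patient perioperative cardiac-
#' surgery cohort, per preoperative MoCA range: columns are patients with a
#' decrease of at least 3/2/1 points, no change, and an increase of at
#' least 1/2/3 points (the threshold columns nest). Used as the default
#' composition of the synthetic cohort and as a bookkeeping fixture.
#'
#' @export
moca_change_reference_counts <- matrix(
  c(4,  9, 13, 4, 15,  8,  6,
    9, 15, 20, 4, 44, 27, 13,
    2,  4,  8, 3,  6,  4,  1),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("lower", "intermediate", "higher"),
                  c("dec_ge3", "dec_ge2", "dec_ge1", "no_change",
                    "inc_ge1", "inc_ge2", "inc_ge3")))

#' Convert nested threshold counts into exact-change cells
#'
#' Inverts the nesting (dec_ge3 within dec_ge2 within dec_ge1, likewise for
#' increases): patients with a change of at least 3 points are generated at
#' exactly +-3.
#'
#' @param counts 3 x 7 matrix shaped like [moca_change_reference_counts].
#' @return Data.frame with columns `range`, `delta`, `n`.
#' @export
cells_from_nested_counts <- function(counts = moca_change_reference_counts) {
  rows <- list()
  for (r in rownames(counts)) {
    cc <- counts[r, ]
    n_by_delta <- c(`-3` = cc[["dec_ge3"]],
                    `-2` = cc[["dec_ge2"]] - cc[["dec_ge3"]],
                    `-1` = cc[["dec_ge1"]] - cc[["dec_ge2"]],
                    `0`  = cc[["no_change"]],
                    `1`  = cc[["inc_ge1"]] - cc[["inc_ge2"]],
                    `2`  = cc[["inc_ge2"]] - cc[["inc_ge3"]],
                    `3`  = cc[["inc_ge3"]])
    if (any(n_by_delta < 0)) stop("counts are not nested for range ", r)
    for (d in names(n_by_delta))
      rows[[length(rows) + 1L]] <- data.frame(
        range = r, delta = as.integer(d), n = unname(n_by_delta[[d]]))
  }
  out <- do.call(rbind, rows)
  out[out$n > 0, ]
}

#' Synthetic cohort generator specification
#'
#' Marker summaries are drawn from normal distributions truncated to
#' `[0, 1]`. Group effects are injected as additive shifts applied to the
#' decrease group (patients with `delta < 0`): `pcei_pre_shift_decrease`
#' raises their preoperative `%CEIm` and `ptensi_post_shift_decrease`
#' raises their postoperative `%TensI-high`, emulating the two headline
#' effect directions. Zero shifts give a null cohort.
#'
#' @param cells Data.frame `range`, `delta`, `n` (exact counts); default
#'   the reference composition.
#' @param pcei_mean,ptensi_mean Baseline marker means (fractions).
#' @param marker_sd Marker SD before truncation.
#' @param pcei_pre_shift_decrease,ptensi_post_shift_decrease Additive
#'   effects for the decrease group.
#' @param age_mean,age_sd Age distribution (years).
#' @param hads_mean,hads_sd Per-subscale HADS distribution (0-21,
#'   truncated).
#' @param seed Integer seed; all draws flow from it.
#' @return List of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(cells = cells_from_nested_counts(),
                            pcei_mean = 0.5, ptensi_mean = 0.3,
                            marker_sd = 0.25,
                            pcei_pre_shift_decrease = 0,
                            ptensi_post_shift_decrease = 0,
                            age_mean = 65, age_sd = 10,
                            hads_mean = 6, hads_sd = 4, seed = 1L) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("range", "delta", "n") %in% names(cells)),
            all(cells$n >= 0), all(cells$range %in% moca_ranges),
            marker_sd > 0, age_sd > 0, hads_sd > 0)
  structure(list(cells = cells, pcei_mean = pcei_mean,
                 ptensi_mean = ptensi_mean, marker_sd = marker_sd,
                 pcei_pre_shift_decrease = pcei_pre_shift_decrease,
                 ptensi_post_shift_decrease = ptensi_post_shift_decrease,
                 age_mean = age_mean, age_sd = age_sd,
                 hads_mean = hads_mean, hads_sd = hads_sd,
                 seed = as.integer(seed)),
            class = "cohort_gen_spec")
}

# Truncated-normal draw on [lo, hi] via inverse CDF (vectorized, exact).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd); phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(runif(n, plo, phi))
}

# Random subscore vector summing to `total`: choose `total` of the 30 unit
# points, each point belonging to one subscore slot.
random_subscores <- function(total) {
  slots <- rep(names(moca_subscore_max), times = moca_subscore_max)
  take <- sample.int(30L, total)
  tab <- table(factor(slots[take], levels = names(moca_subscore_max)))
  as.integer(tab)
}

pre_total_for <- function(range, delta) {
  lims <- switch(range, lower = c(5L, 20L), intermediate = c(21L, 25L),
                 higher = c(26L, 30L))
  lo <- max(lims[1], 0L - delta)
  hi <- min(lims[2], 30L - delta)
  if (lo > hi) stop("no feasible pre total for range ", range, " delta ", delta)
  if (lo == hi) lo else sample(lo:hi, 1L)
}

#' Generate a synthetic per-patient cohort table
#'
#' Deterministic for a fixed spec; realized cell counts are exactly as
#' specified. Subscores sum to their totals; HADS totals are the subscale
#' sums; marker fractions live in `[0, 1]`.
#'
#' @param spec A [cohort_gen_spec()].
#' @return Cohort data.frame with the [cohort_schema()] columns.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  withr::with_seed(spec$seed, {
    rows <- list()
    pid <- 0L
    for (i in seq_len(nrow(spec$cells))) {
      cell <- spec$cells[i, ]
      for (j in seq_len(cell$n)) {
        pid <- pid + 1L
        pre <- pre_total_for(cell$range, cell$delta)
        post <- pre + cell$delta
        sub_pre <- random_subscores(pre)
        sub_post <- random_subscores(post)
        dec <- cell$delta < 0
        pcei_pre_m <- spec$pcei_mean + if (dec) spec$pcei_pre_shift_decrease else 0
        ptensi_post_m <- spec$ptensi_mean + if (dec) spec$ptensi_post_shift_decrease else 0
        anx <- round(rtruncnorm(2, spec$hads_mean, spec$hads_sd, 0, 21))
        dep <- round(rtruncnorm(2, spec$hads_mean, spec$hads_sd, 0, 21))
        row <- data.frame(
          id = sprintf("P%03d", pid),
          age = round(rtruncnorm(1, spec$age_mean, spec$age_sd, 18, 95)),
          sex = sample(c("M", "F"), 1L, prob = c(0.7, 0.3)),
          moca_pre_total = pre, moca_post_total = post,
          stringsAsFactors = FALSE)
        row[paste0("moca_pre_", names(moca_subscore_max))] <- as.list(sub_pre)
        row[paste0("moca_post_", names(moca_subscore_max))] <- as.list(sub_post)
        row$hads_pre_anx <- anx[1]; row$hads_post_anx <- anx[2]
        row$hads_pre_dep <- dep[1]; row$hads_post_dep <- dep[2]
        row$hads_pre_total <- anx[1] + dep[1]
        row$hads_post_total <- anx[2] + dep[2]
        row$pcei_m_pre <- rtruncnorm(1, pcei_pre_m, spec$marker_sd, 0, 1)
        row$pcei_m_post <- rtruncnorm(1, spec$pcei_mean, spec$marker_sd, 0, 1)
        row$ptensi_hi_pre <- rtruncnorm(1, spec$ptensi_mean, spec$marker_sd, 0, 1)
        row$ptensi_hi_post <- rtruncnorm(1, ptensi_post_m, spec$marker_sd, 0, 1)
        rows[[pid]] <- row
      }
    }
    out <- do.call(rbind, rows)
    out[, cohort_schema()]
  })
}

#' The reference synthetic cohort (bookkeeping fixture)
#'
#' A null cohort (no marker effects) whose composition matches
#' [moca_change_reference_counts] exactly.
#'
#' @param seed Integer seed.
#' @return Cohort data.frame.
#' @export
reference_cohort <- function(seed = 1L) {
  generate_cohort(cohort_gen_spec(seed = seed))
}

#' Write a cohort table to CSV
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
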