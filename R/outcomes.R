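#' Band an initial vancomycin trough concentration
#'
#' Troughs are banded against the 10-15 mg/L therapeutic target used for
#' neonatal non-CNS infections: `<10`, `10-15` (both boundaries inclusive)
#' and `>15` mg/L.
#'
#' @param trough_mg_L Numeric vector of trough concentrations (> 0, after
#'   BLQ replacement).
#' @return A factor with levels `"<10"`, `"10-15"`, `">15"`.
#' @examples
#' classify_trough_band(c(8.9, 10, 15, 15.01))
#' @export
classify_trough_band <- function(trough_mg_L) {
  stopifnot(all(trough_mg_L > 0))
  cut(trough_mg_L, breaks = c(0, 10, 15, Inf),
      labels = c("<10", "10-15", ">15"),
      right = FALSE) -> lower
  # right = FALSE puts 15 in ">15"; the target band is inclusive on both
  # sides, so place exact 15s back into 10-15.
  band <- as.character(lower)
  band[trough_mg_L == 15] <- "10-15"
  factor(band, levels = c("<10", "10-15", ">15"))
}

#' Classify acute kidney injury by modified neonatal RIFLE criteria
#'
#' AKI (stage 1 or above) is triggered by any of: an on-therapy serum
#' creatinine rise of >=50% over baseline, an absolute rise of >=27 µmol/L,
#' or oliguria (any recorded urine-output interval < 1 mL/kg/h).  Baseline
#' is the last SCr at or before the course start.  When no baseline SCr is
#' available the assessment falls back to the urine-output criterion alone.
#' Stage is assigned from the peak SCr ratio (>=1.5x stage 1, >=2x stage 2,
#' >=3x stage 3); an absolute-rise or oliguria trigger without a qualifying
#' ratio is stage 1.
#'
#' @param scr_series Data.frame with `time_h` and `scr_umol_L` (may have 0
#'   rows).
#' @param urine_series Data.frame with `rate_ml_kg_h` (per recorded interval;
#'   may have 0 rows).
#' @param course_start_h,course_end_h Course boundaries on the study clock.
#' @return A list of class `aki_assessment`: `aki` (logical), `stage` (0-3),
#'   `trigger` (`"scr_relative"`, `"scr_absolute"`, `"oliguria"` or
#'   `"none"`), `basis` (`"scr"` or `"urine-only"`).
#' @export
assess_aki <- function(scr_series, urine_series,
                       course_start_h = 0, course_end_h = Inf) {
  scr_series <- scr_series %||% data.frame(time_h = numeric(),
                                           scr_umol_L = numeric())
  urine_series <- urine_series %||% data.frame(rate_ml_kg_h = numeric())
  if (nrow(scr_series) == 0 && nrow(urine_series) == 0) {
    stop("need at least one of a creatinine or urine-output series",
         call. = FALSE)
  }
  baseline <- NA_real_
  peak <- NA_real_
  if (nrow(scr_series)) {
    pre <- scr_series$scr_umol_L[scr_series$time_h <= course_start_h]
    if (length(pre)) {
      baseline <- pre[which.max(scr_series$time_h[scr_series$time_h <=
                                                    course_start_h])]
    }
    on_rx <- scr_series$scr_umol_L[scr_series$time_h >= course_start_h &
                                     scr_series$time_h <= course_end_h]
    if (length(on_rx)) peak <- max(on_rx)
  }
  oliguria <- nrow(urine_series) > 0 &&
    any(urine_series$rate_ml_kg_h < 1, na.rm = TRUE)

  trigger <- "none"; stage <- 0L
  basis <- if (is.na(baseline)) "urine-only" else "scr"
  if (!is.na(baseline) && !is.na(peak)) {
    ratio <- peak / baseline
    rise <- peak - baseline
    ratio_stage <- if (ratio >= 3) 3L else if (ratio >= 2) 2L
      else if (ratio >= 1.5) 1L else 0L
    if (rise >= 27) {
      trigger <- "scr_absolute"
      stage <- max(1L, ratio_stage)
    } else if (ratio_stage >= 1L) {
      trigger <- "scr_relative"
      stage <- ratio_stage
    }
  }
  if (stage == 0L && oliguria) {
    trigger <- "oliguria"
    stage <- 1L
  }
  structure(list(aki = stage >= 1L, stage = stage, trigger = trigger,
                 basis = basis), class = "aki_assessment")
}

#' @export
print.aki_assessment <- function(x, ...) {
  cat(sprintf("<aki_assessment> stage %d (%s; basis %s)\n", x$stage,
              x$trigger, x$basis))
  invisible(x)
}

#' Clinical outcomes stratified by initial trough band
#'
#' Counts and percentages of each outcome flag per trough band, restricted
#' to courses of at least `min_duration_days` (default 5 days, the standard
#' eligibility filter for outcome analysis).
#'
#' @param courses Data.frame with `initial_trough_mg_L`, `duration_days`,
#'   and one logical/0-1 column per outcome named in `outcomes`.
#' @param outcomes Character vector of outcome column names; default every
#'   column of `courses` starting with `"flag_"`.
#' @param min_duration_days Minimum course duration retained.
#' @return A data.frame with one row per band x outcome: `band`, `outcome`,
#'   `n` (band size), `events`, `pct` (100*events/n, one decimal).
#' @export
stratified_outcome_table <- function(courses, outcomes = NULL,
                                     min_duration_days = 5) {
  stopifnot(is.data.frame(courses),
            all(c("initial_trough_mg_L", "duration_days") %in%
                  names(courses)))
  if (nrow(courses) == 0) stop("no courses supplied", call. = FALSE)
  outcomes <- outcomes %||% grep("^flag_", names(courses), value = TRUE)
  if (!length(outcomes)) stop("no outcome columns found", call. = FALSE)
  keep <- courses$duration_days >= min_duration_days
  courses <- courses[keep, , drop = FALSE]
  if (nrow(courses) == 0) {
    stop("no courses remain after the duration filter", call. = FALSE)
  }
  band <- classify_trough_band(courses$initial_trough_mg_L)
  rows <- list()
  for (b in levels(band)) {
    in_band <- band == b
    n <- sum(in_band)
    for (oc in outcomes) {
      events <- sum(as.logical(courses[[oc]][in_band]))
      rows[[length(rows) + 1L]] <- data.frame(
        band = b, outcome = oc, n = n, events = events,
        pct = if (n > 0) round(100 * events / n, 1) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for an r x c contingency table
#'
#' Exact two-sided p-value over all tables with the observed margins,
#' summing the hypergeometric probabilities of tables no more probable than
#' the observed one.  Enumeration is delegated to [stats::fisher.test()];
#' tables whose total exceeds `max_total` are refused with a pointer to the
#' Monte-Carlo option.
#'
#' @param table_counts Matrix (or data.frame) of non-negative integer
#'   counts.
#' @param max_total Refuse exact enumeration above this grand total
#'   (default 10000) unless `simulate = TRUE`.
#' @param simulate Use Monte-Carlo p-value estimation instead of exact
#'   enumeration.
#' @param n_replicates Monte-Carlo replicates when `simulate = TRUE`.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_rxc(matrix(c(1, 4, 5, 130, 57, 19), ncol = 2))
#' @export
fisher_exact_rxc <- function(table_counts, max_total = 10000,
                             simulate = FALSE, n_replicates = 1e5) {
  m <- as.matrix(table_counts)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!simulate && sum(m) > max_total) {
    stop(sprintf(
      "table total %d exceeds the exact-enumeration limit (%d); call with simulate = TRUE for a Monte-Carlo p-value",
      sum(m), max_total), call. = FALSE)
  }
  if (simulate) {
    stats::fisher.test(m, simulate.p.value = TRUE, B = n_replicates)$p.value
  } else {
    stats::fisher.test(m, workspace = 2e7)$p.value
  }
}

#' Therapeutic target attainment
#'
#' Percentage of courses whose selected trough lies inside the target band
#' (boundaries inclusive), rounded to whole percent for reporting.
#'
#' @param troughs Numeric vector of trough concentrations (one per course):
#'   initial troughs or post-TDM troughs depending on the question asked.
#' @param band Numeric length-2 target band (mg/L), default `c(10, 15)`.
#' @return A list with `n_total`, `n_in_band` and `pct` (integer percent).
#' @examples
#' target_attainment(c(8, 12, 14, 22))
#' @export
target_attainment <- function(troughs, band = c(10, 15)) {
  stopifnot(is.numeric(troughs), length(band) == 2, band[1] < band[2])
  n <- length(troughs)
  hit <- sum(troughs >= band[1] & troughs <= band[2])
  list(n_total = n, n_in_band = hit,
       pct = if (n > 0) round(100 * hit / n) else NA_real_)
}

#' Rank-based group comparison
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test for two groups, or the
#' Kruskal-Wallis rank-sum test for more than two.  For two untied small
#' samples the p-value is exact by enumeration (the [stats::wilcox.test()]
#' exact path); otherwise a normal / chi-square approximation with tie
#' correction is used, and the `method` field says which.
#'
#' @param groups Either a named list of numeric vectors, or a numeric vector
#'   (with `by` giving group labels).
#' @param by Optional grouping vector when `groups` is numeric.
#' @return A list with `method`, `statistic` and `p_value`.
#' @examples
#' rank_tests(list(a = c(1, 2, 3), b = c(101, 102, 103)))
#' @export
rank_tests <- function(groups, by = NULL) {
  if (is.numeric(groups) && !is.null(by)) {
    groups <- split(groups, by)
  }
  stopifnot(is.list(groups))
  sizes <- vapply(groups, length, integer(1))
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes == 0)) {
    stop(sprintf("empty group(s): %s",
                 paste(names(groups)[sizes == 0], collapse = ", ")),
         call. = FALSE)
  }
  if (length(groups) == 2) {
    ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                              exact = NULL,
                                              correct = TRUE))
    method <- ht$method
  } else {
    ht <- stats::kruskal.test(groups)
    method <- ht$method
  }
  list(method = method, statistic = unname(ht$statistic),
       p_value = ht$p.value)
}
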