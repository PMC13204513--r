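#' Apply the below-quantification-limit (BLQ) replacement rule
#'
#' Concentrations below the assay's lower limit of quantification (default
#' 4 mg/L) are replaced by a fixed imputation value (default 2 mg/L, half the
#' limit) and flagged.  Values at or above the limit pass through unchanged.
#'
#' @param observations A data.frame with a `value_mg_L` column, or a bare
#'   numeric vector.
#' @param limit Lower limit of quantification (mg/L).
#' @param replacement Imputed value for censored observations (mg/L); must be
#'   below `limit`.
#' @return The input with censored values replaced and a logical `bql`
#'   column added (for a vector input, a data.frame with `value_mg_L` and
#'   `bql`).
#' @examples
#' preprocess_blq(c(3.9, 4, 12.2))
#' @export
preprocess_blq <- function(observations, limit = 4, replacement = 2) {
  if (replacement >= limit) {
    stop("BLQ replacement value must be below the quantification limit",
         call. = FALSE)
  }
  if (is.numeric(observations)) {
    observations <- data.frame(value_mg_L = observations)
  }
  stopifnot("value_mg_L" %in% names(observations))
  v <- observations$value_mg_L
  if (any(v < 0, na.rm = TRUE)) {
    stop("raw concentrations must be >= 0", call. = FALSE)
  }
  bql <- !is.na(v) & v < limit
  observations$value_mg_L[bql] <- replacement
  observations$bql <- bql
  observations
}

#' Assemble observed/predicted pairs
#'
#' @param c_obs Observed concentrations (mg/L), after BLQ replacement.
#' @param c_pred Model-predicted concentrations (mg/L).
#' @param ... Further columns (patient_id, covariate strata, ...) recycled to
#'   the common length.
#' @return A data.frame of class `prediction_pairs`.
#' @export
prediction_pairs <- function(c_obs, c_pred, ...) {
  stopifnot(length(c_obs) == length(c_pred))
  if (any(c_obs <= 0)) {
    stop("observed concentrations must be > 0; run preprocess_blq() first",
         call. = FALSE)
  }
  if (any(!is.finite(c_pred) | c_pred < 0)) {
    stop("predictions must be finite and >= 0", call. = FALSE)
  }
  df <- data.frame(c_obs = c_obs, c_pred = c_pred, ...)
  class(df) <- c("prediction_pairs", "data.frame")
  df
}

metric_funs <- list(
  me = function(obs, pred) mean(pred - obs),
  rmse = function(obs, pred) sqrt(mean((pred - obs)^2)),
  rel_me = function(obs, pred) 100 * mean((pred - obs) / obs),
  rel_mde = function(obs, pred) 100 * stats::median((pred - obs) / obs),
  p30 = function(obs, pred) 100 * mean(abs(pred - obs) / obs <= 0.30)
)

#' External predictive-performance metrics
#'
#' Computes the standard a-priori validation metric set over prediction
#' errors `PE_i = C_pred,i - C_obs,i`:
#' mean error `ME = mean(PE)` (bias, mg/L); `RMSE = sqrt(mean(PE^2))`
#' (imprecision, mg/L); relative mean and median error
#' `100 * mean(PE/C_obs)` and `100 * median(PE/C_obs)` (%); and `p30`, the
#' percentage of predictions within 30% of the observed value (boundary
#' inclusive).
#'
#' @param pairs A data.frame with `c_obs` (> 0) and `c_pred` columns.
#' @return A list of class `metric_set` with elements `n`, `me_mg_L`,
#'   `rmse_mg_L`, `rel_me_pct`, `rel_mde_pct`, `p30_pct`.
#' @examples
#' compute_metrics(data.frame(c_obs = c(10, 20), c_pred = c(12, 16)))
#' @export
compute_metrics <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1,
            all(c("c_obs", "c_pred") %in% names(pairs)))
  if (any(pairs$c_obs <= 0)) {
    stop("observed concentrations must be > 0; run preprocess_blq() first",
         call. = FALSE)
  }
  obs <- pairs$c_obs; pred <- pairs$c_pred
  structure(list(
    n = nrow(pairs),
    me_mg_L = metric_funs$me(obs, pred),
    rmse_mg_L = metric_funs$rmse(obs, pred),
    rel_me_pct = metric_funs$rel_me(obs, pred),
    rel_mde_pct = metric_funs$rel_mde(obs, pred),
    p30_pct = metric_funs$p30(obs, pred)), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "<metric_set> n=%d  ME=%.3f mg/L  RMSE=%.3f mg/L  RelME=%.1f%%  RelMdE=%.1f%%  p30=%.1f%%\n",
    x$n, x$me_mg_L, x$rmse_mg_L, x$rel_me_pct, x$rel_mde_pct, x$p30_pct))
  invisible(x)
}

#' Nonparametric bootstrap confidence interval for a validation metric
#'
#' Percentile 95% interval over resamples of the prediction pairs drawn with
#' replacement.  Resampling is at the observation level by default; pass
#' `cluster` to resample whole patients instead (levels are drawn with
#' replacement and all of a drawn patient's observations enter the
#' resample).
#'
#' @param pairs As in [compute_metrics()]; at least 2 rows.
#' @param metric One of `"me"`, `"rmse"`, `"rel_me"`, `"rel_mde"`, `"p30"`.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed Optional integer for reproducible resampling.
#' @param cluster Optional vector (length `nrow(pairs)`) of patient
#'   identifiers for cluster resampling.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(pairs, metric = c("me", "rmse", "rel_me", "rel_mde",
                                           "p30"),
                         n_resamples = 1000, seed = NULL, cluster = NULL,
                         level = 0.95) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(pairs))
  n <- nrow(pairs)
  if (n < 2) stop("bootstrap needs at least 2 prediction pairs",
                  call. = FALSE)
  f <- metric_funs[[metric]]
  obs <- pairs$c_obs; pred <- pairs$c_pred
  with_seed(seed, {
    stat <- if (is.null(cluster)) {
      vapply(seq_len(n_resamples), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        f(obs[idx], pred[idx])
      }, numeric(1))
    } else {
      stopifnot(length(cluster) == n)
      groups <- split(seq_len(n), cluster)
      vapply(seq_len(n_resamples), function(b) {
        idx <- unlist(groups[sample.int(length(groups), length(groups),
                                        replace = TRUE)], use.names = FALSE)
        f(obs[idx], pred[idx])
      }, numeric(1))
    }
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(stat, c(alpha, 1 - alpha), type = 7))
    c(lower = ci[1], upper = ci[2])
  })
}

#' Predefined external-validation acceptance criteria
#'
#' The five predefined thresholds for acceptable a-priori performance in a
#' neonatal TDM cohort: bias `|ME| <= 0.5` mg/L, `|Rel ME| <= 15`%,
#' `|Rel MdE| <= 15`%, `RMSE < 10` mg/L and `p30 > 45`%.  A model meeting
#' all five is classified highly predictive; three or four, moderately
#' predictive; fewer, poor.
#'
#' @param metrics A `metric_set` from [compute_metrics()], or any list /
#'   one-row data.frame with fields `me_mg_L`, `rel_me_pct`, `rel_mde_pct`,
#'   `rmse_mg_L`, `p30_pct`.
#' @return A list of class `criteria_verdict`: logical `flags` (me, rel_me,
#'   rel_mde, rmse, p30), integer `n_met` and `classification`.
#' @examples
#' apply_criteria(list(me_mg_L = -0.46, rel_me_pct = 12.2, rel_mde_pct = 4.2,
#'                     rmse_mg_L = 8.00, p30_pct = 49.3))
#' @export
apply_criteria <- function(metrics) {
  need <- c("me_mg_L", "rel_me_pct", "rel_mde_pct", "rmse_mg_L", "p30_pct")
  if (!all(need %in% names(metrics))) {
    stop("metrics must provide: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  flags <- c(me = abs(metrics$me_mg_L) <= 0.5,
             rel_me = abs(metrics$rel_me_pct) <= 15,
             rel_mde = abs(metrics$rel_mde_pct) <= 15,
             rmse = metrics$rmse_mg_L < 10,
             p30 = metrics$p30_pct > 45)
  n_met <- sum(flags)
  classification <- if (n_met == 5) "highly predictive"
    else if (n_met >= 3) "moderately predictive" else "poor"
  structure(list(flags = flags, n_met = as.integer(n_met),
                 classification = classification),
            class = "criteria_verdict")
}

#' @export
print.criteria_verdict <- function(x, ...) {
  cat(sprintf("<criteria_verdict> %d/5 criteria met (%s): %s\n", x$n_met,
              x$classification,
              paste(names(x$flags)[x$flags], collapse = ", ")))
  invisible(x)
}

#' Rank candidate models by criteria met, then precision, then bias
#'
#' Orders a table of per-model validation metrics by the number of
#' predefined criteria met (descending), breaking ties by lower RMSE and
#' then lower absolute ME; remaining ties keep the input order.
#'
#' @param metric_table A data.frame with a `model` column and the metric
#'   columns of [apply_criteria()].
#' @return The table with `n_met` and `classification` columns appended,
#'   sorted by rank.
#' @export
rank_models <- function(metric_table) {
  stopifnot(is.data.frame(metric_table), nrow(metric_table) >= 1)
  verdicts <- lapply(seq_len(nrow(metric_table)),
                     function(i) apply_criteria(metric_table[i, ]))
  metric_table$n_met <- vapply(verdicts, `[[`, integer(1), "n_met")
  metric_table$classification <- vapply(verdicts, `[[`, character(1),
                                        "classification")
  ord <- order(-metric_table$n_met, metric_table$rmse_mg_L,
               abs(metric_table$me_mg_L))
  out <- metric_table[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Built-in neonatal subgroup definitions
#'
#' The standard developmental strata for residual subgroup analysis:
#' postnatal age (<=7 vs. >7 days), postmenstrual age in five groups
#' (extremely preterm <28, very preterm 28 to <32, moderately preterm 32 to
#' <34, late preterm 34 to <37, term >=37 weeks), weight (<1.5 vs. >=1.5 kg)
#' and serum creatinine (<90 vs. >=90 µmol/L).
#'
#' @return A named list of stratum specs usable by [subgroup_residuals()];
#'   each has `covariate`, `breaks` and `labels`.
#' @export
neonatal_strata <- function() {
  list(
    pna = list(covariate = "pna_days", breaks = c(-Inf, 7, Inf),
               labels = c("<=7 d", ">7 d"), right = TRUE),
    pma = list(covariate = "pma_weeks", breaks = c(-Inf, 28, 32, 34, 37, Inf),
               labels = c("<28 wk", "28-<32 wk", "32-<34 wk", "34-<37 wk",
                          ">=37 wk"), right = FALSE),
    weight = list(covariate = "weight_kg", breaks = c(-Inf, 1.5, Inf),
                  labels = c("<1.5 kg", ">=1.5 kg"), right = FALSE),
    scr = list(covariate = "scr_umol_L", breaks = c(-Inf, 90, Inf),
               labels = c("<90 umol/L", ">=90 umol/L"), right = FALSE)
  )
}

#' Residual summaries and rank tests across covariate strata
#'
#' Residuals (`c_pred - c_obs`) are summarised per stratum (n, median,
#' quartiles) and compared across strata with a two-sided Mann-Whitney U
#' (Wilcoxon rank-sum) test for two groups or a Kruskal-Wallis test for more
#' than two.  Empty strata are dropped with a warning.
#'
#' @param pairs A data.frame with `c_obs`, `c_pred` and the covariate columns
#'   named by `strata`.
#' @param strata A named list of stratum specs (`covariate`, `breaks`,
#'   `labels`, optional `right`); default [neonatal_strata()] restricted to
#'   covariates present in `pairs`.
#' @return A list with one element per stratum variable: `summary` (a
#'   data.frame of per-group n/median/q1/q3), `test` (method name) and
#'   `p_value`.
#' @export
subgroup_residuals <- function(pairs, strata = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("c_obs", "c_pred") %in% names(pairs)))
  if (is.null(strata)) {
    strata <- Filter(function(s) s$covariate %in% names(pairs),
                     neonatal_strata())
  }
  if (!length(strata)) stop("no usable strata", call. = FALSE)
  resid <- pairs$c_pred - pairs$c_obs
  out <- lapply(names(strata), function(sname) {
    s <- strata[[sname]]
    if (!s$covariate %in% names(pairs)) {
      stop(sprintf("stratum covariate '%s' missing from pairs", s$covariate),
           call. = FALSE)
    }
    grp <- cut(pairs[[s$covariate]], breaks = s$breaks, labels = s$labels,
               right = s$right %||% FALSE)
    counts <- table(grp)
    if (any(counts == 0)) {
      warning(sprintf("stratum '%s': empty group(s) %s excluded", sname,
                      paste(names(counts)[counts == 0], collapse = ", ")),
              call. = FALSE)
      grp <- droplevels(grp)
    }
    groups <- split(resid, grp)
    summ <- data.frame(
      group = names(groups),
      n = vapply(groups, length, integer(1)),
      median = vapply(groups, stats::median, numeric(1)),
      q1 = vapply(groups, function(g) unname(stats::quantile(g, 0.25)),
                  numeric(1)),
      q3 = vapply(groups, function(g) unname(stats::quantile(g, 0.75)),
                  numeric(1)),
      row.names = NULL)
    rt <- rank_tests(groups)
    list(summary = summ, test = rt$method, p_value = rt$p_value)
  })
  names(out) <- names(strata)
  out
}
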