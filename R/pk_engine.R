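#' Construct a dosing history
#'
#' A dosing history is an ordered table of intravenous infusion events for a
#' single patient-course.  Doses are assumed to be short infusions (default
#' 1 h, the institutional protocol); the infusion interval is half-open,
#' `[start, start + duration)`.  Overlapping infusions are permitted (their
#' contributions are summed) but flagged with a warning, since they usually
#' indicate a reconstruction error.
#'
#' @param start_time_h Numeric vector of infusion start times, hours on the
#'   study clock (conventionally hours since first dose of the course).
#' @param dose_mg Dose amounts (mg), > 0. Recycled if scalar.
#' @param infusion_duration_h Infusion durations (h), > 0; default 1.
#' @return A `dosing_history`: a data.frame with columns `start_time_h`,
#'   `dose_mg`, `infusion_duration_h`, `rate_mg_h`, sorted by start time.
#' @examples
#' dosing_history(seq(0, 36, by = 12), dose_mg = 10.6)
#' @export
dosing_history <- function(start_time_h, dose_mg, infusion_duration_h = 1) {
  n <- length(start_time_h)
  dose_mg <- rep_len(dose_mg, n)
  infusion_duration_h <- rep_len(infusion_duration_h, n)
  if (any(!is.finite(start_time_h))) {
    stop("dose start times must be finite", call. = FALSE)
  }
  if (any(dose_mg <= 0)) stop("all doses must be > 0 mg", call. = FALSE)
  if (any(infusion_duration_h <= 0)) {
    stop("infusion durations must be > 0 h", call. = FALSE)
  }
  ord <- order(start_time_h)
  h <- data.frame(start_time_h = start_time_h[ord], dose_mg = dose_mg[ord],
                  infusion_duration_h = infusion_duration_h[ord])
  h$rate_mg_h <- h$dose_mg / h$infusion_duration_h
  if (n > 1 && any(h$start_time_h[-1] <
                   h$start_time_h[-n] + h$infusion_duration_h[-n])) {
    warning("overlapping infusions in dosing history; contributions summed",
            call. = FALSE)
  }
  class(h) <- c("dosing_history", "data.frame")
  h
}

#' Concentration under one-compartment intermittent-infusion kinetics
#'
#' Closed-form superposition of zero-order infusions with first-order
#' elimination (the Sawchuk-Zaske short-infusion model).  With `k = CL/V`
#' and a dose infused at rate `R0` from `t0` for `Tinf` hours, the
#' contribution at time `t` is `(R0/CL) (1 - e^{-k (t - t0)})` during the
#' infusion and `(R0/CL) (1 - e^{-k Tinf}) e^{-k (t - t0 - Tinf)}` after it;
#' contributions from all started doses are summed.
#'
#' @param params A `structural_params` (one-compartment) from
#'   [evaluate_model()] or a list with `cl_L_h` and `v_L`.
#' @param history A [dosing_history()].
#' @param t Numeric vector of times (h, study clock).
#' @return Concentrations (mg/L), one per element of `t`.
#' @examples
#' h <- dosing_history(0, 10)
#' concentration_at(list(cl_L_h = 1, v_L = 1), h, c(1, 2))
#' @export
concentration_at <- function(params, history, t) {
  check_one_compartment(params)
  stopifnot(is.data.frame(history), all(is.finite(t)))
  cl <- params$cl_L_h; v <- params$v_L
  k <- cl / v
  out <- numeric(length(t))
  for (i in seq_len(nrow(history))) {
    t0 <- history$start_time_h[i]
    tinf <- history$infusion_duration_h[i]
    r0 <- history$rate_mg_h[i]
    dt <- t - t0
    during <- dt >= 0 & dt < tinf
    after <- dt >= tinf
    out[during] <- out[during] + (r0 / cl) * (1 - exp(-k * dt[during]))
    out[after] <- out[after] +
      (r0 / cl) * (1 - exp(-k * tinf)) * exp(-k * (dt[after] - tinf))
  }
  out
}

check_one_compartment <- function(params) {
  if (!is.null(params$q_L_h) || !is.null(params$vp_L)) {
    stop(paste("two-compartment parameters supplied; the closed-form engine",
               "covers one-compartment models only (register a dedicated",
               "evaluator for two-compartment definitions)"), call. = FALSE)
  }
  if (!is.finite(params$cl_L_h) || params$cl_L_h <= 0 ||
      !is.finite(params$v_L) || params$v_L <= 0) {
    stop("structural parameters must be positive and finite", call. = FALSE)
  }
  invisible(params)
}

#' Steady-state trough for a regular intermittent-infusion regimen
#'
#' Closed-form pre-dose concentration at steady state for identical doses
#' every `tau_h` hours infused over `tinf_h` hours:
#' \deqn{C_{min,ss} = \frac{R_0}{CL} (1 - e^{-k T_{inf}})
#'       \frac{e^{-k(\tau - T_{inf})}}{1 - e^{-k\tau}}}
#'
#' @inheritParams concentration_at
#' @param dose_mg Dose per administration (mg).
#' @param tinf_h Infusion duration (h).
#' @param tau_h Dosing interval (h), must exceed `tinf_h`.
#' @return Steady-state trough concentration (mg/L).
#' @export
steady_state_trough <- function(params, dose_mg, tinf_h = 1, tau_h = 12) {
  check_one_compartment(params)
  if (!(tau_h > tinf_h && tinf_h > 0)) {
    stop("need tau_h > tinf_h > 0", call. = FALSE)
  }
  if (dose_mg <= 0) stop("dose must be > 0", call. = FALSE)
  k <- params$cl_L_h / params$v_L
  r0 <- dose_mg / tinf_h
  (r0 / params$cl_L_h) * (1 - exp(-k * tinf_h)) *
    exp(-k * (tau_h - tinf_h)) / (1 - exp(-k * tau_h))
}

#' Elimination half-life
#'
#' `t1/2 = ln(2) V / CL` for a one-compartment model.
#'
#' @inheritParams concentration_at
#' @return Half-life in hours.
#' @export
half_life <- function(params) {
  check_one_compartment(params)
  log(2) * params$v_L / params$cl_L_h
}

#' Population predictions at observed sampling times
#'
#' The a-priori prediction mode of external validation: for each observation
#' time, structural parameters are evaluated from the most recent covariate
#' snapshot at or before that time (last observation carried forward) and the
#' concentration is computed by [concentration_at()].  No conditioning on the
#' patient's measured levels is performed.
#'
#' @param model A [poppk_model()].
#' @param covariates Either a single [covariate_set()] (time-constant
#'   covariates) or a list of them ordered arbitrarily; each carries its
#'   `measurement_time_h`.
#' @param history A [dosing_history()].
#' @param times Numeric vector of observation times (h, study clock).
#' @return Numeric vector of predicted concentrations (mg/L), one per
#'   observation time; `numeric(0)` for an empty `times`.
#' @export
predict_for_observations <- function(model, covariates, history, times) {
  if (inherits(covariates, "covariate_set")) covariates <- list(covariates)
  stopifnot(length(covariates) >= 1L)
  if (!length(times)) return(numeric(0))
  cov_times <- vapply(covariates, function(cv) cv$measurement_time_h,
                      numeric(1))
  ord <- order(cov_times)
  covariates <- covariates[ord]; cov_times <- cov_times[ord]
  idx <- findInterval(times, cov_times)
  if (any(idx == 0)) {
    stop(sprintf(
      "no covariate record at or before observation time %s h",
      format(min(times[idx == 0]))), call. = FALSE)
  }
  out <- numeric(length(times))
  for (j in unique(idx)) {
    sel <- idx == j
    params <- evaluate_model(model, covariates[[j]])
    out[sel] <- concentration_at(params, history, times[sel])
  }
  out
}
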