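#' Specify a synthetic neonatal vancomycin cohort
#'
#' The generator emulates the study conditions of a retrospective NICU TDM
#' cohort: covariate marginals centred on a very-preterm population (weight
#' mean 1.06 kg, GA mean 26.4 wk, PMA mean 28.9 wk, SCr median 56 µmol/L,
#' urine output mean 3.89 mL/kg/h), the institutional dosing protocol
#' (10 mg/kg per dose, q12h below 30 weeks PMA and q8h at or above, 1 h
#' infusions), trough sampling 30 min before the 4th dose, and the assay BLQ
#' rule (values < 4 mg/L recorded as 2 mg/L).  Weight is linked to GA by a
#' lognormal regression because only marginal summaries are published.
#'
#' @param n_patients Number of neonates (>= 1).
#' @param ga Truncated-normal GA distribution (weeks):
#'   `list(mean, sd, min, max)`.
#' @param pna Truncated-lognormal PNA distribution (days):
#'   `list(meanlog, sdlog, min, max)`.
#' @param weight Weight-from-GA link: `list(mean_kg, slope_per_week, sdlog,
#'   ga_ref)`; log weight = intercept + slope * (GA - ga_ref) + N(0, sdlog^2)
#'   with the intercept set so the analytic mean equals `mean_kg`.
#' @param scr Truncated-lognormal SCr distribution (µmol/L).
#' @param urine Truncated-normal urine output distribution (mL/kg/h).
#' @param dose_mg_kg Protocol dose (mg/kg), default 10.
#' @param pma_cutoff_weeks,interval_below_h,interval_above_h Dosing-interval
#'   rule by PMA: `interval_below_h` when PMA < cutoff, else
#'   `interval_above_h`.
#' @param infusion_duration_h Infusion duration (h), default 1.
#' @param trough_before_dose Trough drawn before this dose number (default
#'   4), `trough_offset_h` hours before its start.
#' @param trough_offset_h Pre-dose sampling offset (h), default 0.5.
#' @param n_troughs Troughs per course (default 1); later troughs precede
#'   every 6th dose after the first sampled one.
#' @param duration_days_range Integer range of course durations (days).
#' @param truth_model The data-generating [poppk_model()] (IIV + residual),
#'   default [chung2023_model()].
#' @param blq_limit,blq_replacement BLQ censoring rule.
#' @param aki_injection Optional `list(prob_by_band = c(...))` of AKI
#'   injection probabilities per trough band (`<10`, `10-15`, `>15`); `NULL`
#'   disables injection and yields threshold-free trajectories.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 100,
                        ga = list(mean = 26.4, sd = 3.22, min = 22,
                                  max = 34),
                        pna = list(meanlog = log(12), sdlog = 0.716,
                                   min = 1, max = 27),
                        weight = list(mean_kg = 1.06, slope_per_week = 0.13,
                                      sdlog = 0.18, ga_ref = 26.4),
                        scr = list(meanlog = log(56), sdlog = 0.528,
                                   min = 15, max = 300),
                        urine = list(mean = 3.89, sd = 1.56, min = 0.5,
                                     max = 10),
                        dose_mg_kg = 10,
                        pma_cutoff_weeks = 30,
                        interval_below_h = 12,
                        interval_above_h = 8,
                        infusion_duration_h = 1,
                        trough_before_dose = 4,
                        trough_offset_h = 0.5,
                        n_troughs = 1,
                        duration_days_range = c(5, 14),
                        truth_model = chung2023_model(),
                        blq_limit = 4,
                        blq_replacement = 2,
                        aki_injection = NULL) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  stopifnot(inherits(truth_model, "poppk_model"),
            interval_below_h > infusion_duration_h,
            interval_above_h > infusion_duration_h,
            trough_before_dose >= 2,
            trough_offset_h > 0,
            duration_days_range[1] >= 1)
  spec <- list(n_patients = as.integer(n_patients), ga = ga, pna = pna,
               weight = weight, scr = scr, urine = urine,
               dose_mg_kg = dose_mg_kg, pma_cutoff_weeks = pma_cutoff_weeks,
               interval_below_h = interval_below_h,
               interval_above_h = interval_above_h,
               infusion_duration_h = infusion_duration_h,
               trough_before_dose = trough_before_dose,
               trough_offset_h = trough_offset_h,
               n_troughs = n_troughs,
               duration_days_range = duration_days_range,
               truth_model = truth_model, blq_limit = blq_limit,
               blq_replacement = blq_replacement,
               aki_injection = aki_injection)
  class(spec) <- "cohort_spec"
  spec
}

# Location parameter whose [min, max]-truncated normal has the given mean,
# so declared covariate means are realized means (no truncation bias).
trunc_norm_location <- function(mean, sd, min, max) {
  trunc_mean <- function(mu) {
    a <- (min - mu) / sd; b <- (max - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  stats::uniroot(function(mu) trunc_mean(mu) - mean,
                 interval = c(min - 3 * sd, max + 3 * sd),
                 tol = 1e-10)$root
}

# MGF of a truncated normal at t (for the weight-from-GA lognormal link).
trunc_norm_mgf <- function(t, mu, sd, min, max) {
  a <- (min - mu) / sd; b <- (max - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  exp(mu * t + sd^2 * t^2 / 2) *
    (stats::pnorm(b - sd * t) - stats::pnorm(a - sd * t)) / z
}

rtrunc_norm <- function(n, mean, sd, min, max) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= min & draw <= max
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

rtrunc_lnorm <- function(n, meanlog, sdlog, min, max) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rlnorm(length(need), meanlog, sdlog)
    ok <- draw >= min & draw <= max
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

protocol_interval <- function(spec, pma_weeks) {
  ifelse(pma_weeks < spec$pma_cutoff_weeks, spec$interval_below_h,
         spec$interval_above_h)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates, builds each course per the dosing protocol, samples
#' individual PK parameters from the truth model's IIV, computes noiseless
#' concentrations at the scheduled trough times, adds residual error per the
#' truth model's residual spec, applies the BLQ rule, and (when configured)
#' injects exposure-dependent AKI trajectories.  Everything is reproducible
#' under `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (private RNG state); `NULL` uses the session RNG.
#' @return A list of class `synthetic_cohort` with data.frames:
#'   \describe{
#'     \item{patients}{one row per neonate: covariates at course start.}
#'     \item{courses}{course bounds, duration, interval, initial trough and
#'       (when injection is configured) the true AKI flag.}
#'     \item{doses}{dose events (`start_time_h`, `dose_mg`,
#'       `infusion_duration_h`).}
#'     \item{levels}{measured troughs after residual error and BLQ
#'       replacement.}
#'     \item{creatinine, urine}{on-therapy SCr and urine-output series.}
#'     \item{truth}{per-patient individual parameters and noiseless
#'       concentrations (for tests; not an observable).}
#'   }
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n_patients
    ga_mu <- trunc_norm_location(spec$ga$mean, spec$ga$sd, spec$ga$min,
                                 spec$ga$max)
    ga <- rtrunc_norm(n, ga_mu, spec$ga$sd, spec$ga$min, spec$ga$max)
    pna <- rtrunc_lnorm(n, spec$pna$meanlog, spec$pna$sdlog, spec$pna$min,
                        spec$pna$max)
    pma <- ga + pna / 7
    # intercept chosen so E[weight] = mean_kg exactly under the truncated-GA
    # law: E[wt] = exp(mu0 + sdlog^2/2) E[exp(slope (GA - ref))]
    b <- spec$weight$slope_per_week
    e_link <- exp(-b * spec$weight$ga_ref) *
      trunc_norm_mgf(b, ga_mu, spec$ga$sd, spec$ga$min, spec$ga$max)
    mu0 <- log(spec$weight$mean_kg) - log(e_link) - spec$weight$sdlog^2 / 2
    wt <- exp(mu0 + b * (ga - spec$weight$ga_ref) +
                stats::rnorm(n, 0, spec$weight$sdlog))
    scr <- rtrunc_lnorm(n, spec$scr$meanlog, spec$scr$sdlog, spec$scr$min,
                        spec$scr$max)
    urine <- rtrunc_norm(n, spec$urine$mean, spec$urine$sd, spec$urine$min,
                         spec$urine$max)
    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      ga_weeks = ga, pna_days = pna, pma_weeks = pma, weight_kg = wt,
      scr_umol_L = scr, urine_output_ml_kg_h = urine)

    duration <- sample(seq(spec$duration_days_range[1],
                           spec$duration_days_range[2]), n, replace = TRUE)
    tau <- protocol_interval(spec, pma)
    dose_mg <- spec$dose_mg_kg * wt

    doses <- vector("list", n); levels <- vector("list", n)
    truth_params <- vector("list", n); truth_conc <- vector("list", n)
    init_trough <- numeric(n)
    m <- spec$truth_model
    add_sd <- m$residual$additive_sd %||% 0
    prop_cv <- m$residual$proportional_cv %||% 0
    for (i in seq_len(n)) {
      n_doses <- floor(duration[i] * 24 / tau[i]) + 1
      t_dose <- (seq_len(n_doses) - 1) * tau[i]
      doses[[i]] <- data.frame(patient_id = patients$patient_id[i],
                               course_id = 1L,
                               start_time_h = t_dose, dose_mg = dose_mg[i],
                               infusion_duration_h =
                                 spec$infusion_duration_h)
      cov <- covariate_set(wt[i], pma[i], pna[i], scr[i], urine[i], 0)
      typ <- evaluate_model(m, cov)
      ind <- typ
      for (p in names(m$iiv)) {
        if (p %in% names(ind) && m$iiv[[p]] > 0) {
          ind[[p]] <- ind[[p]] * exp(stats::rnorm(1, 0, sqrt(m$iiv[[p]])))
        }
      }
      # trough schedule: before dose k, then before every 6th dose after
      ks <- spec$trough_before_dose + 6 * (seq_len(spec$n_troughs) - 1)
      ks <- ks[ks <= n_doses]
      t_obs <- (ks - 1) * tau[i] - spec$trough_offset_h
      hist <- dosing_history(t_dose, dose_mg[i], spec$infusion_duration_h)
      true_c <- concentration_at(ind, hist, t_obs)
      meas <- true_c * (1 + stats::rnorm(length(t_obs), 0, prop_cv)) +
        stats::rnorm(length(t_obs), 0, add_sd)
      meas[meas < 0] <- 0
      bql <- meas < spec$blq_limit
      meas[bql] <- spec$blq_replacement
      levels[[i]] <- data.frame(patient_id = patients$patient_id[i],
                                course_id = 1L, time_h = t_obs,
                                value_mg_L = meas, bql = bql)
      truth_params[[i]] <- data.frame(patient_id = patients$patient_id[i],
                                      cl_L_h = ind$cl_L_h, v_L = ind$v_L)
      truth_conc[[i]] <- data.frame(patient_id = patients$patient_id[i],
                                    time_h = t_obs, true_mg_L = true_c)
      init_trough[i] <- meas[1]
    }
    courses <- data.frame(
      patient_id = patients$patient_id, course_id = 1L,
      start_time_h = 0, end_time_h = duration * 24,
      duration_days = duration, interval_h = tau,
      initial_trough_mg_L = init_trough)
    cohort <- list(patients = patients, courses = courses,
                   doses = do.call(rbind, doses),
                   levels = do.call(rbind, levels),
                   truth = list(params = do.call(rbind, truth_params),
                                concentrations = do.call(rbind, truth_conc)),
                   spec = spec)
    traj <- inject_aki(spec, cohort$courses, patients)
    cohort$creatinine <- traj$creatinine
    cohort$urine <- traj$urine
    cohort$courses$true_aki <- traj$true_aki
    class(cohort) <- "synthetic_cohort"
    cohort
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d doses, %d levels (truth model: %s)\n",
              nrow(x$patients), nrow(x$doses), nrow(x$levels),
              x$spec$truth_model$name))
  invisible(x)
}

#' Inject exposure-dependent AKI trajectories
#'
#' Builds daily serum-creatinine and urine-output series for each course.
#' Courses are selected for AKI with a probability given per initial-trough
#' band (monotone in exposure by construction of the defaults); selected
#' courses receive an SCr ramp crossing the >=50% relative-rise rule (a
#' randomly chosen subset instead receive an oliguric interval), while
#' unselected courses stay strictly below every AKI threshold.
#'
#' @param spec A [cohort_spec()]; `spec$aki_injection$prob_by_band` gives
#'   the three selection probabilities for bands `<10`, `10-15`, `>15`
#'   (all 0 when injection is not configured).
#' @param courses Course table with `initial_trough_mg_L`, `start_time_h`,
#'   `end_time_h`.
#' @param patients Patient table with `scr_umol_L` and
#'   `urine_output_ml_kg_h` baselines.
#' @param seed Optional integer seed.
#' @return A list with `creatinine` and `urine` data.frames and the logical
#'   selection vector `true_aki`.
#' @export
inject_aki <- function(spec, courses, patients, seed = NULL) {
  probs <- spec$aki_injection$prob_by_band %||% c(0, 0, 0)
  stopifnot(length(probs) == 3, all(probs >= 0 & probs <= 1))
  band <- classify_trough_band(pmax(courses$initial_trough_mg_L, 0.1))
  p_sel <- probs[as.integer(band)]
  with_seed(seed, {
    sel <- stats::runif(nrow(courses)) < p_sel
    scr_rows <- vector("list", nrow(courses))
    ur_rows <- vector("list", nrow(courses))
    for (i in seq_len(nrow(courses))) {
      pid <- courses$patient_id[i]
      base_scr <- patients$scr_umol_L[patients$patient_id == pid][1]
      base_ur <- patients$urine_output_ml_kg_h[patients$patient_id ==
                                                 pid][1]
      days <- seq(0, ceiling((courses$end_time_h[i] -
                                courses$start_time_h[i]) / 24))
      t_h <- courses$start_time_h[i] + days * 24
      oliguric <- sel[i] && stats::runif(1) < 0.2
      if (sel[i] && !oliguric) {
        # ramp to a peak 1.6-2.5x baseline mid-course, triggering the
        # relative-rise rule (and usually the absolute-rise rule too)
        peak <- base_scr * stats::runif(1, 1.6, 2.5)
        frac <- pmin(days / max(1, max(days) / 2), 1)
        scr_t <- base_scr + (peak - base_scr) * frac
      } else {
        # wiggle within +/-5%: below the 50% relative and (for baselines in
        # the generator's range) the 27 umol/L absolute rise
        scr_t <- base_scr * stats::runif(length(days), 0.95, 1.05)
        scr_t[1] <- base_scr
      }
      rate <- pmax(1.05, base_ur * stats::runif(length(days), 0.9, 1.1))
      if (oliguric) rate[max(1, length(rate) %/% 2)] <- 0.5
      scr_rows[[i]] <- data.frame(patient_id = pid,
                                  course_id = courses$course_id[i],
                                  time_h = c(courses$start_time_h[i] - 1,
                                             t_h),
                                  scr_umol_L = c(base_scr, scr_t))
      ur_rows[[i]] <- data.frame(patient_id = pid,
                                 course_id = courses$course_id[i],
                                 interval_start_h = t_h,
                                 interval_end_h = t_h + 24,
                                 rate_ml_kg_h = rate)
    }
    list(creatinine = do.call(rbind, scr_rows),
         urine = do.call(rbind, ur_rows), true_aki = sel)
  })
}
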