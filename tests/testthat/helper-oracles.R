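# Independent oracles and shared fixtures for the test suite.

# Numerical ODE oracle for one-compartment infusion kinetics: integrates
# dA/dt = rate_in(t) - (CL/V) A segment by segment (rate constant within each
# segment), restarting at every infusion boundary so discontinuities never
# degrade accuracy.  Independent of the closed-form engine under test.
ode_concentration <- function(cl_L_h, v_L, history, times) {
  skip_if_not_installed("deSolve")
  k <- cl_L_h / v_L
  bounds <- sort(unique(c(0, history$start_time_h,
                          history$start_time_h + history$infusion_duration_h,
                          times)))
  bounds <- bounds[bounds >= 0]
  rate_at <- function(t) {
    active <- t >= history$start_time_h &
      t < history$start_time_h + history$infusion_duration_h
    sum(history$rate_mg_h[active])
  }
  amt <- 0
  conc <- stats::setNames(numeric(length(times)), NULL)
  conc[times <= bounds[1]] <- 0
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    if (t1 <= t0) next
    r <- rate_at((t0 + t1) / 2)
    sol <- deSolve::ode(y = c(A = amt), times = c(t0, t1),
                        func = function(t, y, p) list(r - k * y[1]),
                        parms = NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-12)
    amt <- unname(sol[nrow(sol), 2])
    hit <- which(abs(times - t1) < 1e-12)
    conc[hit] <- amt / v_L
  }
  conc
}

# Random intermittent-infusion regimen for property tests.
random_regimen <- function() {
  n_doses <- sample(2:6, 1)
  tau <- stats::runif(1, 4, 24)
  tinf <- stats::runif(1, 0.25, min(2, tau / 2))
  dose <- stats::runif(1, 5, 50)
  dosing_history(start_time_h = (seq_len(n_doses) - 1) * tau,
                 dose_mg = dose, infusion_duration_h = tinf)
}

# Full-enumeration Fisher oracle for 2x2 tables: two-sided p as the sum of
# hypergeometric probabilities of tables (same margins) no more probable
# than the observed one.
fisher_2x2_enumeration <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Published external-validation metric rows for the six best-performing
# neonatal vancomycin models (observed cohort summary; bundled fixture).
published_metric_table <- function() {
  path <- system.file("extdata", "published_validation_metrics.csv",
                      package = "neovanc")
  utils::read.csv(path, check.names = FALSE)
}

# Trough-band outcome counts from the same cohort: 216 courses of >=5 days
# split 131 / 61 / 24 across the <10, 10-15 and >15 mg/L bands.
outcome_fixture_courses <- function() {
  band_n <- c(131, 61, 24)
  troughs <- rep(c(8, 12, 20), band_n)
  persistent <- c(rep(TRUE, 6), rep(FALSE, 131 - 6),
                  rep(TRUE, 2), rep(FALSE, 61 - 2),
                  rep(FALSE, 24))
  aki <- c(rep(TRUE, 1), rep(FALSE, 131 - 1),
           rep(TRUE, 4), rep(FALSE, 61 - 4),
           rep(TRUE, 5), rep(FALSE, 24 - 5))
  data.frame(patient_id = sprintf("C%03d", seq_along(troughs)),
             initial_trough_mg_L = troughs, duration_days = 7,
             flag_persistent_culture = persistent, flag_aki = aki)
}
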