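test_that("Chung 2023 clearance reproduces its defining values", {
  # maturation term -> 1 as PMA grows: asymptote is the 13.9 L/h base
  cov_inf <- covariate_set(70, 1e15, scr_umol_L = 34)
  expect_equal(chung2023_typical_clearance(cov_inf), 13.9, tolerance = 1e-9)
  # half-maximal maturation at PMA = TM50 = 47.7 weeks
  cov_half <- covariate_set(70, 47.7, scr_umol_L = 34)
  expect_equal(chung2023_typical_clearance(cov_half), 6.95)
  # cohort-mean covariates, frozen high-precision arithmetic oracle
  cov_mean <- covariate_set(1.06, 28.9, scr_umol_L = 56)
  expect_equal(chung2023_typical_clearance(cov_mean), 0.0620681504574793,
               tolerance = 1e-12)
})

test_that("Chung 2023 volume is linear in weight from the 65.5 L reference", {
  expect_equal(chung2023_typical_volume(covariate_set(70, 40)), 65.5)
  expect_equal(chung2023_typical_volume(covariate_set(35, 40)), 32.75)
  expect_equal(chung2023_typical_volume(covariate_set(1.06, 28.9)),
               0.991857142857143, tolerance = 1e-12)
})

test_that("invalid covariates are refused at the boundary", {
  expect_error(covariate_set(0, 30), "weight_kg")
  expect_error(covariate_set(1, -5), "pma_weeks")
  expect_error(covariate_set(1, 30, scr_umol_L = -1), "scr_umol_L")
  expect_error(covariate_set(1, 30, pna_days = -1), "pna_days")
  expect_error(
    chung2023_typical_clearance(covariate_set(1, 30)), "creatinine")
})

test_that("the registry evaluation of the built-in model matches the dedicated equations", {
  m <- chung2023_model()
  grid <- expand.grid(wt = c(0.5, 1.06, 2, 4), pma = c(24, 28.9, 34, 44),
                      scr = c(20, 34, 56, 120))
  for (i in seq_len(nrow(grid))) {
    cov <- covariate_set(grid$wt[i], grid$pma[i], scr_umol_L = grid$scr[i])
    p <- evaluate_model(m, cov)
    expect_equal(p$cl_L_h, chung2023_typical_clearance(cov),
                 tolerance = 1e-12)
    expect_equal(p$v_L, chung2023_typical_volume(cov), tolerance = 1e-12)
  }
})

test_that("declared term kinds evaluate correctly in toy models", {
  allo <- poppk_model("allo", 1, params = list(
    cl_L_h = list(base = 2, terms = list(
      list(kind = "power", covariate = "weight_kg", ref = 70,
           exponent = 0.75))),
    v_L = list(base = 40)))
  p <- evaluate_model(allo, covariate_set(70, 40))
  expect_equal(p$cl_L_h, 2)
  expect_equal(p$v_L, 40)

  # power SCr term with exponent -1: doubling SCr halves the base
  scr_m <- poppk_model("scr-toy", 1, params = list(
    cl_L_h = list(base = 2, terms = list(
      list(kind = "power", covariate = "scr_umol_L", ref = 34,
           exponent = -1))),
    v_L = list(base = 40)))
  p2 <- evaluate_model(scr_m, covariate_set(70, 40, scr_umol_L = 68))
  expect_equal(p2$cl_L_h, 2 * 0.5)

  lin <- poppk_model("lin", 1, params = list(
    cl_L_h = list(base = 1, terms = list(
      list(kind = "linear", covariate = "pna_days", ref = 0,
           slope = 0.01))),
    v_L = list(base = 40)))
  expect_equal(
    evaluate_model(lin, covariate_set(1, 30, pna_days = 10))$cl_L_h, 1.1)
})

test_that("a missing model covariate raises an error naming the symbol", {
  m <- chung2023_model()
  expect_error(evaluate_model(m, covariate_set(1, 30)), "scr_umol_L")
})

test_that("Chung clearance is monotone in each covariate and the maturation term bounded", {
  cl_at <- function(wt, pma, scr)
    chung2023_typical_clearance(covariate_set(wt, pma, scr_umol_L = scr))
  pma_grid <- seq(22, 60, by = 2)
  expect_true(all(diff(vapply(pma_grid, function(p) cl_at(1, p, 50),
                              numeric(1))) > 0))
  wt_grid <- seq(0.5, 4, by = 0.25)
  expect_true(all(diff(vapply(wt_grid, function(w) cl_at(w, 30, 50),
                              numeric(1))) > 0))
  scr_grid <- seq(20, 200, by = 10)
  expect_true(all(diff(vapply(scr_grid, function(s) cl_at(1, 30, s),
                              numeric(1))) < 0))
  hill <- function(pma) pma^0.739 / (pma^0.739 + 47.7^0.739)
  expect_true(all(hill(c(0.01, 1, 47.7, 1e6)) > 0 &
                    hill(c(0.01, 1, 47.7, 1e6)) < 1))
})

test_that("individual-parameter sampling honours variance, seed and the zero-IIV case", {
  cov <- covariate_set(1.06, 28.9, scr_umol_L = 56)
  m0 <- chung2023_model(iiv = c(cl_L_h = 0, v_L = 0))
  typ <- evaluate_model(m0, cov)
  smp <- sample_individual_params(m0, cov, seed = 1)
  expect_equal(smp$cl_L_h, typ$cl_L_h)
  expect_equal(smp$v_L, typ$v_L)

  m <- chung2023_model(iiv = c(cl_L_h = 0.09))
  expect_identical(sample_individual_params(m, cov, seed = 7),
                   sample_individual_params(m, cov, seed = 7))

  # law of large numbers: mean log(CL_i / CL_typ) -> 0
  set.seed(11)
  draws <- replicate(4000,
                     log(sample_individual_params(m, cov)$cl_L_h /
                           typ$cl_L_h))
  expect_lt(abs(mean(draws)), 3 * 0.3 / sqrt(4000))
  expect_equal(stats::sd(draws), 0.3, tolerance = 0.1)

  no_iiv <- poppk_model("bare", 1,
                        params = list(cl_L_h = list(base = 1),
                                      v_L = list(base = 1)))
  expect_error(sample_individual_params(no_iiv, cov), "zero variances")
})

test_that("the shipped model definition file matches the built-in definition", {
  path <- system.file("extdata", "models", "chung2023.yaml",
                      package = "neovanc")
  m_file <- read_model_def(path)
  m_builtin <- chung2023_model()
  cov <- covariate_set(0.87, 27.5, scr_umol_L = 61)
  expect_equal(evaluate_model(m_file, cov), evaluate_model(m_builtin, cov),
               tolerance = 1e-15)
  expect_equal(m_file$iiv, m_builtin$iiv)
})

test_that("malformed model declarations are rejected", {
  expect_error(poppk_model("x", 1, params = list(cl_L_h = list(base = 1))),
               "v_L")
  expect_error(poppk_model("x", 2, params = list(cl_L_h = list(base = 1),
                                                 v_L = list(base = 1))),
               "2-compartment")
  expect_error(poppk_model("x", 1, params = list(
    cl_L_h = list(base = -1), v_L = list(base = 1))), "positive")
  expect_error(poppk_model("x", 1, params = list(
    cl_L_h = list(base = 1, terms = list(list(kind = "spline",
                                              covariate = "weight_kg"))),
    v_L = list(base = 1))), "spline")
})
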