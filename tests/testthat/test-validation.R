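test_that("BLQ preprocessing replaces only sub-limit values and flags them", {
  out <- preprocess_blq(c(3.9, 4.0, 12.2))
  expect_equal(out$value_mg_L, c(2, 4.0, 12.2))
  expect_equal(out$bql, c(TRUE, FALSE, FALSE))
  expect_error(preprocess_blq(c(1, 2), limit = 4, replacement = 5),
               "below the quantification limit")
  expect_error(preprocess_blq(c(-1, 2)), ">= 0")
})

test_that("the five metrics match hand arithmetic", {
  perfect <- data.frame(c_obs = c(5, 10, 20), c_pred = c(5, 10, 20))
  m <- compute_metrics(perfect)
  expect_equal(m$me_mg_L, 0)
  expect_equal(m$rmse_mg_L, 0)
  expect_equal(m$rel_me_pct, 0)
  expect_equal(m$rel_mde_pct, 0)
  expect_equal(m$p30_pct, 100)

  two <- compute_metrics(data.frame(c_obs = c(10, 20),
                                    c_pred = c(12, 16)))
  expect_equal(two$me_mg_L, -1.0)
  expect_equal(two$rmse_mg_L, sqrt(10))
  expect_equal(two$rel_me_pct, 0)    # +20% and -20% cancel
  expect_equal(two$rel_mde_pct, 0)
  expect_equal(two$p30_pct, 100)

  one <- compute_metrics(data.frame(c_obs = 10, c_pred = 14))
  expect_equal(one$me_mg_L, 4)
  expect_equal(one$rmse_mg_L, 4)
  expect_equal(one$rel_me_pct, 40)
  expect_equal(one$rel_mde_pct, 40)
  expect_equal(one$p30_pct, 0)

  expect_error(compute_metrics(data.frame(c_obs = c(0, 1),
                                          c_pred = c(1, 1))),
               "preprocess_blq")
})

test_that("RMSE dominates |ME| and p30 is permutation invariant", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    pairs <- data.frame(c_obs = stats::runif(n, 2, 30),
                        c_pred = stats::runif(n, 0, 30))
    m <- compute_metrics(pairs)
    expect_gte(m$rmse_mg_L, abs(m$me_mg_L))
    perm <- pairs[sample.int(n), ]
    expect_equal(compute_metrics(perm)$p30_pct, m$p30_pct)
  }
})

test_that("p30 treats the 30% boundary as inside", {
  m <- compute_metrics(data.frame(c_obs = 10, c_pred = 13))
  expect_equal(m$p30_pct, 100)
})

test_that("bootstrap intervals are seeded, degenerate for constant error, and cluster-aware", {
  pairs <- data.frame(c_obs = rep(10, 20), c_pred = rep(12, 20))
  ci <- bootstrap_ci(pairs, "me", n_resamples = 200, seed = 1)
  expect_equal(unname(ci), c(2, 2))

  set.seed(5)
  noisy <- data.frame(c_obs = stats::runif(30, 5, 20))
  noisy$c_pred <- noisy$c_obs + stats::rnorm(30)
  expect_identical(bootstrap_ci(noisy, "rmse", seed = 42),
                   bootstrap_ci(noisy, "rmse", seed = 42))
  cl_ci <- bootstrap_ci(noisy, "me", seed = 42,
                        cluster = rep(1:6, each = 5))
  expect_lt(cl_ci["lower"], cl_ci["upper"])
  expect_error(bootstrap_ci(noisy[1, , drop = FALSE], "me"), "at least 2")
})

test_that("the predefined criteria reproduce the published per-model counts", {
  tab <- published_metric_table()
  verdicts <- lapply(seq_len(nrow(tab)), function(i) apply_criteria(tab[i, ]))
  expect_equal(vapply(verdicts, `[[`, integer(1), "n_met"), tab$reported_n_met)
  expect_equal(verdicts[[1]]$classification, "highly predictive")
  expect_true(all(vapply(verdicts[-1], `[[`, character(1),
                         "classification") == "moderately predictive"))
})

test_that("criteria boundaries follow their printed form", {
  base <- list(me_mg_L = 0, rel_me_pct = 0, rel_mde_pct = 0, rmse_mg_L = 5,
               p30_pct = 60)
  at_me <- modifyList(base, list(me_mg_L = 0.5))
  expect_true(apply_criteria(at_me)$flags[["me"]])       # within +/-0.5
  at_rel <- modifyList(base, list(rel_me_pct = -15))
  expect_true(apply_criteria(at_rel)$flags[["rel_me"]])  # within +/-15
  at_rmse <- modifyList(base, list(rmse_mg_L = 10))
  expect_false(apply_criteria(at_rmse)$flags[["rmse"]])  # strict < 10
  at_p30 <- modifyList(base, list(p30_pct = 45))
  expect_false(apply_criteria(at_p30)$flags[["p30"]])    # strict > 45
  poor <- modifyList(base, list(me_mg_L = 2, rel_me_pct = 40,
                                rel_mde_pct = 40))
  expect_equal(apply_criteria(poor)$classification, "poor")
})

test_that("model ranking orders by criteria met with RMSE and |ME| tie-breaks", {
  tab <- published_metric_table()
  shuffled <- tab[c(4, 1, 6, 2, 3, 5), ]
  ranked <- rank_models(shuffled)
  expect_equal(ranked$model[1], "Chung 2023")
  expect_equal(ranked$n_met, c(5, 4, 3, 3, 3, 3))
  # the four 3-criteria models order by ascending RMSE
  expect_equal(ranked$model[3:6],
               c("Jung 2021", "Germovsek 2019", "Marques-Minana 2010",
                 "De Hoog 2000")[order(c(8.41, 8.38, 8.78, 9.36))])

  same <- data.frame(model = c("a", "b"), me_mg_L = 0, rel_me_pct = 0,
                     rel_mde_pct = 0, rmse_mg_L = 5, p30_pct = 60)
  expect_equal(rank_models(same)$model, c("a", "b"))
  expect_equal(rank_models(same[1, ])$model, "a")
})

test_that("subgroup residual analysis summarises strata and applies the right rank test", {
  # identical residual multisets in the two weight strata -> p = 1
  pairs <- data.frame(c_obs = rep(10, 6),
                      c_pred = 10 + c(1, 2, 3, 1, 2, 3),
                      weight_kg = c(1, 1, 1, 2, 2, 2))
  res <- subgroup_residuals(pairs,
    strata = list(weight = list(covariate = "weight_kg",
                                breaks = c(-Inf, 1.5, Inf),
                                labels = c("<1.5 kg", ">=1.5 kg"))))
  expect_equal(res$weight$p_value, 1)
  expect_equal(res$weight$summary$n, c(3L, 3L))
  expect_equal(res$weight$summary$median, c(2, 2))

  # fully separated residuals -> exact two-sided p = 0.1 (2 of 20 orderings)
  sep <- data.frame(c_obs = rep(10, 6),
                    c_pred = 10 + c(1, 2, 3, 101, 102, 103),
                    weight_kg = c(1, 1, 1, 2, 2, 2))
  res2 <- subgroup_residuals(sep,
    strata = list(weight = list(covariate = "weight_kg",
                                breaks = c(-Inf, 1.5, Inf),
                                labels = c("<1.5 kg", ">=1.5 kg"))))
  expect_equal(res2$weight$p_value, 0.1)

  # five PMA tiers with one empty -> warning, Kruskal-Wallis on four
  pma_pairs <- data.frame(c_obs = rep(10, 8),
                          c_pred = 10 + stats::rnorm(8),
                          pma_weeks = c(26, 27, 29, 31, 33, 33.5, 35, 36))
  expect_warning(res3 <- subgroup_residuals(pma_pairs,
                                            strata = neonatal_strata()["pma"]),
                 "empty")
  expect_match(res3$pma$test, "Kruskal")
  expect_equal(nrow(res3$pma$summary), 4)
})
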