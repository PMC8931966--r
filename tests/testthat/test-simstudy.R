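test_that("closed-form true RMST matches known values and quadrature", {
  # exponential rate 1 at the 75th percentile
  expect_equal(true_rmst(arm_weibull_rate(1, 1), log(4)), 0.75,
               tolerance = 1e-12)
  # arm with rate e: closed-form exponential integral
  expect_equal(true_rmst(arm_weibull_rate(exp(1), 1), log(4)),
               (1 - 4^(-exp(1))) / exp(1), tolerance = 1e-12)
  # piecewise exponential, hand-computed two-segment integral
  law <- arm_pexp(c(0.125, 0.01), 1)
  hand <- (1 - exp(-0.125)) / 0.125 +
    exp(-0.125) * (1 - exp(-0.01)) / 0.01
  expect_equal(true_rmst(law, 2), hand, tolerance = 1e-12)

  # adaptive quadrature agreement for every built-in scenario law
  for (k in 1:5) {
    sc <- builtin_scenario(k)
    for (law in list(sc$arm0, sc$arm1)) {
      tau <- law_quantile(law, 0.9)
      quad <- integrate(function(t) law_survival(law, t), 0, tau,
                        rel.tol = 1e-10)$value
      expect_equal(true_rmst(law, tau), quad, tolerance = 1e-8)
    }
  }
})

test_that("the true difference curve vanishes at the origin", {
  for (k in 1:5) {
    sc <- builtin_scenario(k)
    d <- true_difference(sc$arm0, sc$arm1)
    expect_equal(d(1e-8), 0, tolerance = 1e-7)
  }
})

test_that("single-tau cell recovers the null effect (small replicate run)", {
  res <- run_table1_cell(delta = 1, beta_b = 0, p = 0.75, n = 100,
                         method = "single_tau", reps = 60, seed = 71)
  expect_equal(res$reps_used + res$n_excluded, 60L)
  expect_lt(abs(res$bias_beta1), 3 * res$mc_se_beta1)
  expect_equal(res$beta0_true, 0.75, tolerance = 1e-12)
})

test_that("single-tau estimator equals the KM plug-in group difference", {
  # with Z the only covariate the GEE fit must equal the group-wise
  # KM RMST difference computed by an independent plug-in route
  set.seed(72)
  sp <- scenario_spec(arm_weibull_rate(1, 1), arm_weibull_rate(exp(1), 1),
                      censoring = cens_exponential(0.25))
  smp <- simulate_sample(sp, 120)
  tau <- log(4)
  pv <- pseudo_values(smp, tau)
  long <- expand_data(pv, smp)
  fit <- fit_gee(long, build_design(model_spec("dummy", covariates = "Z"),
                                    long))
  g0 <- oracle_km_area(smp$time[smp$Z == 0], smp$event[smp$Z == 0], tau)
  g1 <- oracle_km_area(smp$time[smp$Z == 1], smp$event[smp$Z == 1], tau)
  # pseudo-value group means differ from per-group KM plug-ins (the
  # jackknife is on the pooled sample), but the fitted difference must
  # agree with the pooled-jackknife group means to 1e-9
  x <- pv$values[, 1]
  expect_equal(unname(coef(fit)["Z"]),
               mean(x[smp$Z == 1]) - mean(x[smp$Z == 0]),
               tolerance = 1e-9)
  # and track the plug-in difference closely at this n
  expect_lt(abs(coef(fit)["Z"] - (g1 - g0)), 0.2)
})

test_that("vector-method cell runs, selects df, and counts exclusions", {
  res <- run_table1_cell(delta = 1, beta_b = 0, p = 0.75, n = 120,
                         method = "vector", reps = 10, seed = 73,
                         df_range = 3:4)
  expect_equal(res$reps_used + res$n_excluded, 10L)
  expect_true(res$n_extrapolated >= 0)
  expect_lt(abs(res$bias_beta1), max(0.05, 4 * res$mc_se_beta1))
})

test_that("band study reports coverage, length and bias in range", {
  res <- run_table2_scenario(builtin_scenario(3), n_per_group = 60,
                             reps = 12, seed = 74, df_range = 4:5,
                             draws = 2e3)
  expect_true(res$coverage >= 0 && res$coverage <= 1)
  expect_gt(res$mean_length, 0)
  expect_gt(res$mean_abs_bias, 0)
  expect_equal(res$reps_used + res$n_excluded, 12L)
})

test_that("study runners are deterministic under a fixed seed", {
  a <- run_table1_cell(1, 0, 0.75, 60, "single_tau", reps = 15, seed = 75)
  b <- run_table1_cell(1, 0, 0.75, 60, "single_tau", reps = 15, seed = 75)
  expect_equal(a$bias_beta0, b$bias_beta0, tolerance = 1e-15)
  expect_equal(a$bias_beta1, b$bias_beta1, tolerance = 1e-15)
})

test_that("study_summary flattens results to one tidy row", {
  res <- run_table1_cell(1, 0, 0.75, 60, "single_tau", reps = 5, seed = 76)
  row <- study_summary(res)
  expect_equal(nrow(row), 1L)
  expect_true(all(c("bias_beta0", "bias_beta1", "reps_used") %in%
                    names(row)))
})
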