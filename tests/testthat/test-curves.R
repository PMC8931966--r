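fitted_two_arm <- function(n = 80, M = 5, df = NULL, seed = 60) {
  smp <- random_two_arm(n, seed = seed)
  taus <- suppressWarnings(
    choose_time_grid(smp, M = M, lower_q = 0.05, upper_q = 0.95))
  pv <- suppressWarnings(pseudo_values(smp, taus))
  long <- expand_data(pv, smp)
  spec <- if (is.null(df)) model_spec("dummy", covariates = "Z")
          else model_spec("spline", df = df, covariates = "Z")
  list(fit = fit_gee(long, build_design(spec, long)), taus = taus,
       pv = pv, smp = smp)
}

test_that("dummy-time difference curve is gamma + zeta_j", {
  d <- fitted_two_arm()
  cv <- difference_curve(d$fit, "Z")
  b <- coef(d$fit)
  expect_equal(cv$estimate[1], unname(b["Z"]))
  for (j in 2:length(d$taus))
    expect_equal(cv$estimate[j],
                 unname(b["Z"] + b[paste0("I(t", j, "):Z")]))
})

test_that("spline contrast at a basis zero reduces to the main effect", {
  d <- fitted_two_arm(df = 2)
  # at the lower boundary knot the natural-spline columns are (0, 0)
  t0 <- min(d$taus)
  B <- rmstpv:::basis_eval(d$fit$design$info, t0)
  skip_if_not(all(abs(B) < 1e-10))
  cv <- difference_curve(d$fit, "Z", eval_times = t0)
  expect_equal(cv$estimate, unname(coef(d$fit)["Z"]))
  expect_equal(cv$se, sqrt(d$fit$robust_cov["Z", "Z"]), tolerance = 1e-12)
})

test_that("curve variance equals the explicit contrast quadratic form", {
  d <- fitted_two_arm(df = 2)
  t1 <- median(d$taus)
  cv <- difference_curve(d$fit, "Z", eval_times = t1)
  B <- rmstpv:::basis_eval(d$fit$design$info, t1)
  idx <- c("Z", "b1(t):Z", "b2(t):Z")
  cvec <- c(1, B[1, 1], B[1, 2])
  V3 <- d$fit$robust_cov[idx, idx]
  expect_equal(cv$se^2, drop(t(cvec) %*% V3 %*% cvec), tolerance = 1e-10)
  expect_equal(cv$estimate, drop(cvec %*% coef(d$fit)[idx]),
               tolerance = 1e-10)
})

test_that("no extrapolation outside the grid unless requested", {
  d <- fitted_two_arm(df = 2)
  expect_error(difference_curve(d$fit, "Z", eval_times = max(d$taus) + 1),
               "outside")
  cv <- difference_curve(d$fit, "Z", eval_times = max(d$taus) + 1,
                         allow_extrapolation = TRUE)
  expect_true(is.finite(cv$estimate))
})

test_that("single-point and perfectly correlated bands use the normal quantile", {
  d <- fitted_two_arm(df = 2)
  cv1 <- difference_curve(d$fit, "Z", eval_times = median(d$taus))
  b1 <- simultaneous_band(d$fit, cv1, k_grid = 1, draws = 1e4, seed = 1)
  expect_equal(b1$u_level, qnorm(0.975), tolerance = 1e-9)

  # rank-1 contrast covariance: max over grid of identical |z|
  fit1 <- d$fit
  v <- fit1$robust_cov[, "Z"]
  fit1$robust_cov <- tcrossprod(v) / fit1$robust_cov["Z", "Z"]
  cvr <- difference_curve(fit1, "Z")
  br <- simultaneous_band(fit1, cvr, k_grid = 50, draws = 2e5, seed = 2)
  expect_equal(br$u_level, qnorm(0.975), tolerance = 0.02)
})

test_that("critical value grows with the grid and the band contains the CI", {
  d <- fitted_two_arm(n = 120, df = 3, seed = 61)
  cv <- difference_curve(d$fit, "Z")
  u <- vapply(c(2, 10, 100), function(k)
    simultaneous_band(d$fit, cv, k_grid = k, draws = 5e4,
                      seed = 3)$u_level, numeric(1))
  expect_gt(u[3], qnorm(0.975))
  expect_true(all(diff(u) > -0.02))   # monotone within MC error

  band <- simultaneous_band(d$fit, cv, k_grid = 100, draws = 5e4, seed = 3)
  expect_true(all(band$band_lo <= band$ci_lo + 1e-12))
  expect_true(all(band$band_hi >= band$ci_hi - 1e-12))
})

test_that("the MC critical value is stable across seeds", {
  d <- fitted_two_arm(n = 120, df = 3, seed = 62)
  cv <- difference_curve(d$fit, "Z")
  u1 <- simultaneous_band(d$fit, cv, k_grid = 20, draws = 2e5,
                          seed = 100)$u_level
  u2 <- simultaneous_band(d$fit, cv, k_grid = 20, draws = 2e5,
                          seed = 200)$u_level
  expect_equal(u1, u2, tolerance = 0.005)
})

test_that("band draws do not disturb the global RNG stream", {
  d <- fitted_two_arm(df = 2)
  cv <- difference_curve(d$fit, "Z")
  set.seed(77)
  x1 <- runif(1)
  set.seed(77)
  invisible(simultaneous_band(d$fit, cv, k_grid = 5, draws = 1e3, seed = 9))
  expect_identical(runif(1), x1)
})

test_that("covers checks band inclusion at every time, bounds inclusive", {
  d <- fitted_two_arm(df = 2)
  cv <- simultaneous_band(d$fit,
                          difference_curve(d$fit, "Z"),
                          k_grid = 10, draws = 1e4, seed = 4)
  expect_true(covers(cv, function(t) approx(cv$eval_times, cv$estimate,
                                            t)$y))
  above <- cv$band_hi + c(rep(0, length(cv$eval_times) - 1), 1)
  expect_false(covers(cv, above))
  # zero-width degenerate band at the estimate is covered (inclusive)
  cv0 <- cv
  cv0$band_lo <- cv0$band_hi <- cv0$estimate
  expect_true(covers(cv0, cv0$estimate))
})

test_that("curve export has the documented columns", {
  d <- fitted_two_arm(df = 2)
  cv <- simultaneous_band(d$fit, difference_curve(d$fit, "Z"),
                          k_grid = 5, draws = 1e3, seed = 5)
  df <- as.data.frame(cv)
  expect_named(df, c("time", "estimate", "se", "ci_lo", "ci_hi",
                     "band_lo", "band_hi", "u"))
})
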