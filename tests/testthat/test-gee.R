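two_arm_long <- function(n = 60, M = 4, seed = 50) {
  smp <- random_two_arm(n, seed = seed)
  taus <- suppressWarnings(
    choose_time_grid(smp, M = M, lower_q = 0.05, upper_q = 0.95))
  pv <- suppressWarnings(pseudo_values(smp, taus))
  list(smp = smp, pv = pv, taus = taus, long = expand_data(pv, smp))
}

test_that("identity/independence GEE equals ordinary least squares", {
  d <- two_arm_long()
  des <- build_design(model_spec("dummy", covariates = "Z"), d$long)
  fit <- fit_gee(d$long, des)
  ols <- qr.solve(des$X, d$long$pseudo_value)
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-10)
})

test_that("intercept-only single-tau fit is the KM RMST with iid sandwich", {
  d <- two_arm_long()
  tau <- d$taus[2]
  pv <- pseudo_values(d$smp, tau)
  long <- expand_data(pv, d$smp)
  fit <- fit_gee(long, build_design(model_spec("dummy"), long))
  expect_equal(unname(fit$beta[1]), rmst(km_fit(d$smp), tau),
               tolerance = 1e-10)
  # iid sandwich of a mean: sum((x - xbar)^2)/n^2
  x <- pv$values[, 1]
  expect_equal(unname(fit$robust_cov[1, 1]),
               sum((x - mean(x))^2) / length(x)^2, tolerance = 1e-12)
})

test_that("single-tau binary fit equals group-wise pseudo-value means", {
  d <- two_arm_long()
  tau <- d$taus[2]
  pv <- pseudo_values(d$smp, tau)
  long <- expand_data(pv, d$smp)
  fit <- fit_gee(long, build_design(model_spec("dummy", covariates = "Z"),
                                    long))
  x <- pv$values[, 1]
  expect_equal(unname(fit$beta["Z"]),
               mean(x[d$smp$Z == 1]) - mean(x[d$smp$Z == 0]),
               tolerance = 1e-10)
})

test_that("robust covariance matches the term-by-term sandwich oracle", {
  for (seed in c(51, 52)) {
    d <- two_arm_long(seed = seed)
    des <- build_design(model_spec("spline", df = 2, covariates = "Z"),
                        d$long)
    fit <- fit_gee(d$long, des)
    expect_equal(fit$robust_cov,
                 oracle_sandwich(des$X, d$long$pseudo_value, d$long$id,
                                 fit$beta),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # symmetric PSD
    expect_equal(fit$robust_cov, t(fit$robust_cov))
    expect_true(all(eigen(fit$robust_cov, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-12))
  }
})

test_that("sandwich is invariant to subject and within-subject reordering", {
  d <- two_arm_long()
  des <- build_design(model_spec("dummy", covariates = "Z"), d$long)
  fit <- fit_gee(d$long, des)
  perm <- sample(nrow(d$long))
  long2 <- d$long[perm, ]
  attr(long2, "taus") <- attr(d$long, "taus")
  des2 <- build_design(model_spec("dummy", covariates = "Z"), long2)
  fit2 <- fit_gee(long2, des2)
  expect_equal(fit$robust_cov, fit2$robust_cov, tolerance = 1e-10)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-10)
})

test_that("fit_gee enforces preconditions", {
  d <- two_arm_long()
  des <- build_design(model_spec("dummy", covariates = "Z"), d$long)
  one <- d$long[d$long$id == 1, ]
  expect_error(fit_gee(one, des), "row counts|2 subjects")
})

test_that("QIC penalizes roughly the parameter count for iid residuals", {
  # uncensored single tau: pseudo-values are iid min(T, tau)
  set.seed(55)
  n <- 4000
  Z <- rbinom(n, 1, 0.5)
  smp <- survival_sample(rexp(n, exp(0.3 * Z)), rep(1, n),
                         data.frame(Z = Z))
  pv <- pseudo_values(smp, 1.5)
  long <- expand_data(pv, smp)
  fit <- fit_gee(long, build_design(model_spec("dummy", covariates = "Z"),
                                    long))
  tr <- (qic(fit) - fit$residual_ss) / 2
  expect_equal(tr, 2, tolerance = 0.15)
  expect_equal(qic(fit, penalty = "2p") - fit$residual_ss, 4)
})

test_that("QIC is deterministic and ranks nested fits reproducibly", {
  qic_gap <- function() {
    d <- two_arm_long(seed = 56)
    f1 <- fit_gee(d$long, build_design(model_spec("spline", df = 2,
                                                  covariates = "Z"), d$long))
    f2 <- fit_gee(d$long, build_design(model_spec("spline", df = 3,
                                                  covariates = "Z"), d$long))
    expect_gt(qic(f1), 0)
    qic(f1) - qic(f2)
  }
  expect_identical(qic_gap(), qic_gap())
})

test_that("select_spline_df returns the single candidate and a valid fit", {
  d <- two_arm_long(n = 80, M = 8, seed = 57)
  sel <- select_spline_df(d$long, model_spec("spline", df = 3,
                                             covariates = "Z"),
                          df_range = 3)
  expect_equal(sel$best_df, 3L)
  expect_s3_class(sel$fit, "gee_fit")
  # infeasible large df candidates are skipped, not fatal
  sel2 <- select_spline_df(d$long, model_spec("spline", df = 3,
                                              covariates = "Z"),
                           df_range = c(3, 50))
  expect_equal(sel2$best_df, 3L)
  expect_true(is.na(sel2$trace$qic[2]))
})
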