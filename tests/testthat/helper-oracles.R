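# Independent oracles used across the suite. None of these share code with
# the package implementation paths they check.

# area under a Kaplan-Meier curve fitted with survival::survfit, by direct
# summation of the step segments (extends at the last value)
oracle_km_area <- function(time, event, tau) {
  f <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- f$n.event > 0
  tt <- c(0, f$time[keep])
  ss <- c(1, f$surv[keep])
  up <- c(tt[-1], Inf)
  sum(ss * pmax(0, pmin(tau, up) - tt))
}

# naive jackknife pseudo-values: n leave-one-out survfit refits per tau
oracle_pseudo_values <- function(time, event, taus) {
  n <- length(time)
  sapply(taus, function(tau) {
    full <- oracle_km_area(time, event, tau)
    vapply(seq_len(n), function(i) {
      n * full - (n - 1) * oracle_km_area(time[-i], event[-i], tau)
    }, numeric(1))
  })
}

# term-by-term sandwich covariance: bread = sum_i (Z_i' Z_i) over cluster
# blocks, meat = sum_i U_i U_i' with U_i = Z_i' (y_i - Z_i beta), assembled
# with explicit per-cluster loops
oracle_sandwich <- function(X, y, id, beta) {
  p <- ncol(X)
  I_mat <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (g in unique(id)) {
    rows <- which(id == g)
    Zi <- X[rows, , drop = FALSE]
    ri <- y[rows] - Zi %*% beta
    I_mat <- I_mat + t(Zi) %*% Zi
    Ui <- t(Zi) %*% ri
    meat <- meat + Ui %*% t(Ui)
  }
  Ib <- solve(I_mat)
  Ib %*% meat %*% Ib
}

# random right-censored sample with optional ties (rounding)
random_censored_sample <- function(n, tie = TRUE, cens_rate = 0.3,
                                   event_rate = 0.25) {
  t_ev <- rexp(n, event_rate)
  t_c <- rexp(n, cens_rate)
  tm <- pmin(t_ev, t_c)
  if (tie) tm <- round(tm, 1) + 0.05
  survival_sample(tm, as.numeric(t_ev <= t_c))
}

# small two-arm sample with a binary covariate
random_two_arm <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.2 * exp(0.5 * Z))
  t_c <- rexp(n, 0.08)
  survival_sample(round(pmin(t_ev, t_c), 1) + 0.05,
                  as.numeric(t_ev <= t_c), data.frame(Z = Z))
}
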