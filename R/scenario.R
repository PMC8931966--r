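#' Censoring specifications
#'
#' A censoring spec states the censoring law family and the *marginal*
#' censoring fraction it should produce; the law's free parameter (the
#' exponential rate or the uniform upper bound) is solved for by
#' \code{\link{calibrate_censoring}} so that the probability of observing
#' a censored time, integrated over the arm mixture, equals the target.
#'
#' @param fraction target censoring fraction in (0, 1).
#' @return an object of class \code{"censoring_spec"}.
#' @name censoring
NULL

#' @rdname censoring
#' @export
cens_exponential <- function(fraction) {
  stopifnot(is.numeric(fraction), fraction > 0, fraction < 1)
  structure(list(family = "exponential", fraction = fraction),
            class = "censoring_spec")
}

#' @rdname censoring
#' @export
cens_uniform <- function(fraction) {
  stopifnot(is.numeric(fraction), fraction > 0, fraction < 1)
  structure(list(family = "uniform", fraction = fraction),
            class = "censoring_spec")
}

#' @rdname censoring
#' @export
cens_none <- function() {
  structure(list(family = "none", fraction = 0), class = "censoring_spec")
}

#' Two-arm simulation scenario
#'
#' Bundles the per-arm event-time laws, the censoring specification and
#' the allocation probability of arm 1. The arm label is carried as a
#' binary covariate \code{Z} (0 = arm 0, 1 = arm 1).
#'
#' @param arm0,arm1 \code{\link{arm_laws}} objects.
#' @param censoring a \code{\link{censoring}} spec (default none).
#' @param allocation P(Z = 1), in (0, 1).
#' @return an object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(arm0, arm1 = arm0, censoring = cens_none(),
                          allocation = 0.5) {
  stopifnot(inherits(arm0, "arm_law"), inherits(arm1, "arm_law"),
            inherits(censoring, "censoring_spec"),
            allocation > 0, allocation < 1)
  structure(list(arm0 = arm0, arm1 = arm1, censoring = censoring,
                 allocation = allocation),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>\n  arm 0:", x$arm0$label, "\n  arm 1:", x$arm1$label,
      sprintf("\n  censoring: %s (%.0f%%), P(arm 1) = %g\n",
              x$censoring$family, 100 * x$censoring$fraction, x$allocation))
  invisible(x)
}

# mixture survival over the two arms
mixture_survival <- function(spec, t) {
  (1 - spec$allocation) * law_survival(spec$arm0, t) +
    spec$allocation * law_survival(spec$arm1, t)
}

mixture_rmst <- function(spec, tau) {
  (1 - spec$allocation) * true_rmst(spec$arm0, tau) +
    spec$allocation * true_rmst(spec$arm1, tau)
}

#' Solve the censoring-law parameter for a target censoring fraction
#'
#' For exponential censoring with rate r, the marginal censoring
#' probability is \eqn{\int_0^\infty r e^{-rt} \bar S(t) dt} where
#' \eqn{\bar S} is the arm-mixture event-time survival function; for
#' uniform censoring on [0, b] it is the mixture RMST at b divided by b.
#' The parameter is found by root-finding to within 1e-9.
#'
#' @param spec a \code{\link{scenario_spec}} whose censoring spec names the
#'   family and target fraction.
#' @param target_fraction optional override of the spec's target, in (0, 1).
#' @return the exponential rate or uniform upper bound, a single number.
#' @examples
#' sp <- scenario_spec(arm_exponential(1), censoring = cens_exponential(0.25))
#' calibrate_censoring(sp)   # = 1/3: r/(1+r) = 0.25
#' @export
calibrate_censoring <- function(spec, target_fraction = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  family <- spec$censoring$family
  if (family == "none")
    stop("cannot calibrate a 'none' censoring specification")
  target <- if (is.null(target_fraction)) spec$censoring$fraction
            else target_fraction
  if (!is.numeric(target) || target <= 0 || target >= 1)
    stop("target censoring fraction must be in (0, 1)")
  if (family == "exponential") {
    # P(cens) = E_C[Sbar(C)]; integrate on the censoring-quantile scale
    # u = F_C(t) so the integrand is bounded for any rate
    pcens <- function(lograte) {
      r <- exp(lograte)
      stats::integrate(function(u) mixture_survival(spec, -log1p(-u) / r),
                       0, 1, rel.tol = 1e-10)$value
    }
    f <- function(lr) pcens(lr) - target
    root <- stats::uniroot(f, lower = -30, upper = 30, tol = 1e-12,
                           extendInt = "upX")
    return(exp(root$root))
  }
  # uniform on [0, b]: P(cens) = mixture_rmst(b) / b, decreasing in b
  f <- function(logb) {
    b <- exp(logb)
    mixture_rmst(spec, b) / b - target
  }
  root <- stats::uniroot(f, lower = -30, upper = 30, tol = 1e-12,
                         extendInt = "downX")
  exp(root$root)
}

#' Simulate a right-censored two-arm sample
#'
#' Draws arm labels Z ~ Bernoulli(allocation) (or exactly balanced groups),
#' event times from the arm's law, and independent censoring times from the
#' calibrated censoring law; the observed time is the minimum and the event
#' indicator flags whether the event came first.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param n number of subjects (>= 2).
#' @param seed optional integer seed; if \code{NULL} the current RNG stream
#'   is used.
#' @param balanced if \code{TRUE}, assign exactly \code{round(n*allocation)}
#'   subjects to arm 1 instead of Bernoulli sampling.
#' @param cens_param optional pre-computed censoring parameter (rate or
#'   upper bound) to avoid re-calibration in replicated studies.
#' @return a \code{\link{survival_sample}} with binary covariate \code{Z}.
#' @export
simulate_sample <- function(spec, n, seed = NULL, balanced = FALSE,
                            cens_param = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  Z <- if (balanced) {
    n1 <- round(n * spec$allocation)
    sample(rep(c(0L, 1L), c(n - n1, n1)))
  } else stats::rbinom(n, 1L, spec$allocation)
  T0 <- law_sample(spec$arm0, n)
  T1 <- law_sample(spec$arm1, n)
  Tev <- ifelse(Z == 1L, T1, T0)
  fam <- spec$censoring$family
  if (fam == "none") {
    return(survival_sample(Tev, rep(1, n), data.frame(Z = Z)))
  }
  if (is.null(cens_param)) cens_param <- calibrate_censoring(spec)
  C <- switch(fam,
    exponential = stats::rexp(n, rate = cens_param),
    uniform     = stats::runif(n, 0, cens_param))
  survival_sample(pmin(Tev, C), as.numeric(Tev <= C), data.frame(Z = Z))
}

#' Built-in crossing-hazards simulation scenarios
#'
#' Five two-arm scenarios with non-proportional (mostly crossing) hazards,
#' all with 20\% uniform censoring and 1:1 allocation:
#' \describe{
#'   \item{1}{Weibull(rate 0.18, shape 1.5) vs Weibull(rate 0.20, shape
#'     0.75), rate-shape convention S(t) = exp(-rate t^shape).}
#'   \item{2}{Weibull(shape 2.5, scale 30) vs piecewise exponential with
#'     hazard 0.125 before t = 1 and 0.01 after.}
#'   \item{3}{Exponential(1/12) vs piecewise exponential with hazard 0.25
#'     before t = 2 and 1/35 after.}
#'   \item{4}{Weibull(shape 1.5, scale 5) vs piecewise exponential with
#'     hazard 0.5 before t = 1.5 and 0.1 after.}
#'   \item{5}{Weibull(shape 1.6, scale 110) vs piecewise exponential with
#'     hazards 0.0025 / 0.01 / 0.003 on [0,12) / [12,30) / [30,Inf).}
#' }
#' The two printed Weibull numbers are read as (rate, shape) for scenario 1
#' and (shape, scale) for scenarios 2, 4 and 5; that is the reading under
#' which the five survival-curve patterns show the intended crossings (see
#' the methods vignette).
#'
#' @param k scenario number, 1-5.
#' @return a \code{\link{scenario_spec}}.
#' @export
builtin_scenario <- function(k) {
  stopifnot(k %in% 1:5)
  arms <- switch(as.character(k),
    "1" = list(arm_weibull_rate(0.18, 1.5), arm_weibull_rate(0.20, 0.75)),
    "2" = list(arm_weibull(2.5, 30), arm_pexp(c(0.125, 0.01), 1)),
    "3" = list(arm_exponential(1 / 12), arm_pexp(c(0.25, 1 / 35), 2)),
    "4" = list(arm_weibull(1.5, 5), arm_pexp(c(0.5, 0.1), 1.5)),
    "5" = list(arm_weibull(1.6, 110),
               arm_pexp(c(0.0025, 0.01, 0.003), c(12, 30))))
  scenario_spec(arms[[1]], arms[[2]], censoring = cens_uniform(0.20),
                allocation = 0.5)
}
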