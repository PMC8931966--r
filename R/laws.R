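#' Event-time distributions for survival simulation
#'
#' Constructors for the parametric event-time laws used by the simulation
#' scenarios: Weibull in either of its two common conventions, the
#' exponential, and the piecewise exponential. Each law knows its survival
#' function, quantile function, sampler and closed-form restricted mean,
#' so simulation truth never relies on Monte Carlo.
#'
#' Two Weibull conventions are supported and always named explicitly:
#' \itemize{
#'   \item \code{arm_weibull(shape, scale)}: S(t) = exp(-(t/scale)^shape),
#'     the parametrization of \code{\link[stats]{rweibull}};
#'   \item \code{arm_weibull_rate(rate, shape)}: S(t) = exp(-rate * t^shape),
#'     the "scale parameter lambda, shape delta" convention common in the
#'     pseudo-value simulation literature. Internally converted via
#'     scale = rate^(-1/shape).
#' }
#'
#' @param shape,scale,rate positive law parameters (see conventions above).
#' @param rates for \code{arm_pexp}, vector of positive hazard levels.
#' @param cuts for \code{arm_pexp}, strictly increasing interior cut points;
#'   \code{length(cuts) == length(rates) - 1}. Hazard is \code{rates[j]} on
#'   the j-th interval.
#' @return An object of class \code{"arm_law"}.
#' @examples
#' law <- arm_weibull_rate(rate = 1, shape = 1)   # standard exponential
#' true_rmst(law, log(4))                         # = 0.75
#' @name arm_laws
NULL

new_arm_law <- function(type, params, label) {
  structure(list(type = type, params = params, label = label),
            class = "arm_law")
}

#' @rdname arm_laws
#' @export
arm_weibull <- function(shape, scale) {
  stopifnot(is.numeric(shape), shape > 0, is.numeric(scale), scale > 0)
  new_arm_law("weibull", list(shape = shape, scale = scale),
              sprintf("Weibull(shape=%g, scale=%g)", shape, scale))
}

#' @rdname arm_laws
#' @export
arm_weibull_rate <- function(rate, shape) {
  stopifnot(is.numeric(rate), rate > 0, is.numeric(shape), shape > 0)
  law <- arm_weibull(shape = shape, scale = rate^(-1 / shape))
  law$label <- sprintf("Weibull(rate=%g, shape=%g)", rate, shape)
  law
}

#' @rdname arm_laws
#' @export
arm_exponential <- function(rate) {
  stopifnot(is.numeric(rate), rate > 0)
  law <- arm_weibull(shape = 1, scale = 1 / rate)
  law$label <- sprintf("Exponential(rate=%g)", rate)
  law
}

#' @rdname arm_laws
#' @export
arm_pexp <- function(rates, cuts = numeric(0)) {
  stopifnot(is.numeric(rates), all(rates > 0),
            length(cuts) == length(rates) - 1L)
  if (length(cuts) && any(diff(c(0, cuts)) <= 0))
    stop("`cuts` must be strictly increasing and positive")
  new_arm_law("pexp", list(rates = rates, cuts = cuts),
              sprintf("PiecewiseExp(%s)", paste(signif(rates, 4), collapse = ", ")))
}

#' @export
print.arm_law <- function(x, ...) {
  cat("<arm_law>", x$label, "\n")
  invisible(x)
}

#' Survival function of an event-time law
#'
#' @param law an \code{\link{arm_laws}} object.
#' @param t non-negative times.
#' @return S(t) = P(T > t), vectorized over \code{t}.
#' @export
law_survival <- function(law, t) {
  stopifnot(inherits(law, "arm_law"))
  t <- pmax(t, 0)
  switch(law$type,
    weibull = exp(-(t / law$params$scale)^law$params$shape),
    pexp    = exp(-pexp_cumhaz(law, t)),
    stop("unknown law type"))
}

# cumulative hazard of a piecewise-exponential law, vectorized
pexp_cumhaz <- function(law, t) {
  rates <- law$params$rates
  lower <- c(0, law$params$cuts)
  upper <- c(law$params$cuts, Inf)
  H <- numeric(length(t))
  for (j in seq_along(rates)) {
    H <- H + rates[j] * pmax(0, pmin(t, upper[j]) - lower[j])
  }
  H
}

#' Quantile function of an event-time law
#'
#' @inheritParams law_survival
#' @param p probabilities in [0, 1).
#' @return times t with P(T <= t) = p.
#' @export
law_quantile <- function(law, p) {
  stopifnot(inherits(law, "arm_law"), all(p >= 0), all(p < 1))
  switch(law$type,
    weibull = stats::qweibull(p, shape = law$params$shape,
                              scale = law$params$scale),
    pexp = {
      # invert H(t) = -log(1 - p) piecewise
      target <- -log(1 - p)
      rates <- law$params$rates
      lower <- c(0, law$params$cuts)
      Hlow <- pexp_cumhaz(law, lower)
      out <- numeric(length(target))
      for (i in seq_along(target)) {
        j <- max(which(Hlow <= target[i]))
        out[i] <- lower[j] + (target[i] - Hlow[j]) / rates[j]
      }
      out
    })
}

#' Sample event times from a law
#'
#' @inheritParams law_survival
#' @param n number of draws.
#' @return numeric vector of event times. Uses the current RNG stream.
#' @export
law_sample <- function(law, n) {
  stopifnot(inherits(law, "arm_law"))
  switch(law$type,
    weibull = stats::rweibull(n, shape = law$params$shape,
                              scale = law$params$scale),
    pexp    = law_quantile(law, stats::runif(n)))
}

#' Closed-form restricted mean survival time of a law
#'
#' The exact integral of the survival function on [0, tau]. For Weibull
#' laws this is the lower-incomplete-gamma expression
#' \deqn{\int_0^\tau e^{-\lambda t^\delta} dt =
#'   \frac{\lambda^{-1/\delta}}{\delta}\,\gamma(1/\delta, \lambda\tau^\delta)}
#' (with lambda = scale^(-shape), delta = shape); for piecewise-exponential
#' laws it is the exact segment-wise integral of exp(-H(t)). This is the
#' "truth" oracle for all simulation studies; tests cross-check it against
#' adaptive quadrature.
#'
#' @inheritParams law_survival
#' @param tau positive restriction time (vectorized).
#' @return RMST(tau) for the law.
#' @export
true_rmst <- function(law, tau) {
  stopifnot(inherits(law, "arm_law"), all(tau > 0))
  switch(law$type,
    weibull = {
      delta <- law$params$shape
      lambda <- law$params$scale^(-delta)
      a <- 1 / delta
      # gamma(a) * pgamma(x, a) is the lower incomplete gamma function
      lambda^(-a) / delta * gamma(a) * stats::pgamma(lambda * tau^delta, a)
    },
    pexp = {
      rates <- law$params$rates
      lower <- c(0, law$params$cuts)
      upper <- c(law$params$cuts, Inf)
      Slow <- law_survival(law, lower)
      out <- numeric(length(tau))
      for (j in seq_along(rates)) {
        w <- pmax(0, pmin(tau, upper[j]) - lower[j])
        out <- out + Slow[j] * (1 - exp(-rates[j] * w)) / rates[j]
      }
      out
    })
}

#' True RMST-difference curve between two laws
#'
#' @param law0,law1 \code{\link{arm_laws}} objects for the reference arm
#'   (coded 0) and the comparison arm (coded 1).
#' @return a function of t returning RMST_1(t) - RMST_0(t).
#' @export
true_difference <- function(law0, law1) {
  force(law0); force(law1)
  function(t) true_rmst(law1, t) - true_rmst(law0, t)
}
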