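#' Kaplan-Meier estimate as a step survival function
#'
#' Fits the product-limit estimator (via \code{\link[survival]{survfit}})
#' and returns it as a right-continuous step function: jump times (the
#' distinct event times), the survival probability just after each jump,
#' and the largest observed follow-up time. At tied times, events precede
#' censorings (the standard risk-set convention).
#'
#' @param sample a \code{\link{survival_sample}} (or anything with
#'   \code{time}/\code{event} columns).
#' @return an object of class \code{"step_survival"} with fields
#'   \code{jump_times}, \code{values}, \code{max_follow_up}.
#' @examples
#' s <- survival_sample(c(1, 2, 4), c(1, 1, 1))
#' km_fit(s)   # S = 2/3 on [1,2), 1/3 on [2,4), 0 after
#' @export
km_fit <- function(sample) {
  if (is.null(sample$time) || nrow(sample) < 1L) stop("no subjects")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(sample))
  keep <- fit$n.event > 0
  structure(list(jump_times = fit$time[keep],
                 values = fit$surv[keep],
                 max_follow_up = max(sample$time)),
            class = "step_survival")
}

#' @export
print.step_survival <- function(x, ...) {
  cat(sprintf("<step_survival> %d jumps, S(last) = %.4f, max follow-up %.4g\n",
              length(x$jump_times),
              if (length(x$values)) x$values[length(x$values)] else 1,
              x$max_follow_up))
  invisible(x)
}

#' Evaluate a step survival function
#' @param surv a \code{"step_survival"}.
#' @param t times (vectorized). Beyond the last jump S keeps its last value.
#' @return S(t).
#' @export
surv_at <- function(surv, t) {
  stopifnot(inherits(surv, "step_survival"))
  vals <- c(1, surv$values)
  idx <- findInterval(t, surv$jump_times) + 1L
  vals[idx]
}

#' Restricted mean survival time of a step survival function
#'
#' The exact area under the step function on [0, tau]. If tau exceeds the
#' maximum follow-up time and the curve has not reached zero, the curve is
#' extended at its last value and a warning is emitted (the estimate is
#' then an extrapolation).
#'
#' @param surv a \code{"step_survival"} from \code{\link{km_fit}}.
#' @param tau positive restriction time(s).
#' @return RMST(tau), vectorized over tau.
#' @export
rmst <- function(surv, tau) {
  stopifnot(inherits(surv, "step_survival"))
  if (any(tau <= 0)) stop("`tau` must be positive")
  last_val <- if (length(surv$values)) surv$values[length(surv$values)] else 1
  if (any(tau > surv$max_follow_up) && last_val > 0)
    warning("tau exceeds the maximum follow-up time; ",
            "survival curve extended at its last value")
  steps <- c(0, surv$jump_times)
  vals <- c(1, surv$values)
  vapply(tau, function(tt) {
    upper <- c(surv$jump_times, Inf)
    sum(vals * pmax(0, pmin(tt, upper) - steps))
  }, numeric(1))
}

#' Restriction-time grid at event-time quantiles
#'
#' Returns M equally spaced (in probability) quantiles of the observed
#' event-time distribution between \code{lower_q} and \code{upper_q}.
#' Duplicate quantiles (heavily tied data) are collapsed with a warning,
#' so the grid may be shorter than M.
#'
#' @param sample a \code{\link{survival_sample}}.
#' @param M number of restriction times (>= 1).
#' @param lower_q,upper_q probability bounds of the quantile range;
#'   defaults 0.01 and 0.99.
#' @return strictly increasing numeric vector of restriction times.
#' @export
choose_time_grid <- function(sample, M = 16L, lower_q = 0.01,
                             upper_q = 0.99) {
  stopifnot(M >= 1, lower_q >= 0, upper_q > lower_q, upper_q <= 1)
  ev <- sample$time[sample$event == 1]
  if (!length(ev)) stop("no observed events: cannot place a time grid")
  if (length(unique(ev)) < M)
    warning("fewer distinct event times than requested grid points")
  taus <- unname(stats::quantile(ev, probs = seq(lower_q, upper_q,
                                                 length.out = M)))
  out <- unique(taus)
  if (length(out) < length(taus))
    warning("tied event times: grid reduced to ", length(out), " points")
  out
}
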