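#' RMST difference curve from a fitted pseudo-value model
#'
#' Assembles the estimated difference in RMST attributable to a (typically
#' binary 0/1) covariate as a function of follow-up time,
#' \eqn{D(t) = c(t)'\hat\beta}, together with its robust standard error
#' \eqn{\sqrt{c(t)' \hat V c(t)}} and pointwise normal confidence limits.
#' The contrast vector c(t) collects the covariate's main effect, its
#' time-interaction terms evaluated at t, and — when the model contains
#' interactions with effect modifiers — those terms at the fixed modifier
#' values supplied in \code{at} (e.g. the treatment difference at a given
#' age).
#'
#' @param fit a \code{\link{fit_gee}} result.
#' @param covariate name of the covariate whose RMST difference is wanted.
#' @param at named list of fixed values for effect modifiers appearing in
#'   interaction terms with \code{covariate} (default: all 0).
#' @param eval_times evaluation times; default the model's restriction-time
#'   grid. Must lie inside the grid range unless
#'   \code{allow_extrapolation = TRUE} (extrapolated values carry no band).
#' @param level confidence level for the pointwise interval.
#' @param allow_extrapolation permit evaluation outside the grid range
#'   (natural splines extrapolate linearly).
#' @return an object of class \code{"rmst_curve"}: eval_times, contrast
#'   matrix, estimate, se, pointwise \code{ci_lo}/\code{ci_hi}; band slots
#'   empty until \code{\link{simultaneous_band}} is applied.
#' @export
difference_curve <- function(fit, covariate, at = list(), eval_times = NULL,
                             level = 0.95, allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "gee_fit"))
  design <- fit$design
  taus <- design$info$taus
  if (is.null(eval_times)) eval_times <- taus
  rng <- range(taus)
  if (!allow_extrapolation &&
      (any(eval_times < rng[1] - 1e-10) || any(eval_times > rng[2] + 1e-10)))
    stop("evaluation times outside the restriction-time grid [",
         signif(rng[1], 4), ", ", signif(rng[2], 4),
         "]; no extrapolation of the curve")
  C <- contrast_matrix(design, covariate, at, eval_times)
  est <- drop(C %*% fit$beta)
  V <- fit$robust_cov
  se <- sqrt(pmax(0, rowSums((C %*% V) * C)))
  z <- stats::qnorm((1 + level) / 2)
  structure(list(eval_times = eval_times, contrast_matrix = C,
                 estimate = est, se = se,
                 ci_lo = est - z * se, ci_hi = est + z * se,
                 band_lo = NULL, band_hi = NULL, u_level = NULL,
                 level = level, covariate = covariate, at = at,
                 fit = fit),
            class = "rmst_curve")
}

# rows c(t)' for the difference in the mean model per unit of `covariate`,
# holding the modifiers in `at` fixed
contrast_matrix <- function(design, covariate, at, eval_times) {
  cols <- design$cols
  involved <- vapply(cols, function(cl) covariate %in% cl$covs, logical(1))
  if (!any(involved))
    stop("covariate '", covariate, "' has no terms in the fitted model")
  B <- basis_eval(design$info, eval_times)
  C <- matrix(0, length(eval_times), length(cols),
              dimnames = list(NULL, vapply(cols, `[[`, character(1), "label")))
  for (k in which(involved)) {
    cl <- cols[[k]]
    others <- setdiff(cl$covs, covariate)
    w <- 1
    for (v in others) {
      if (is.null(at[[v]]))
        stop("term '", cl$label, "' needs a fixed value for modifier '", v,
             "' in `at`")
      w <- w * at[[v]]
    }
    C[, k] <- if (cl$time == 0L) w else w * B[, cl$time]
  }
  C
}

#' Model-predicted RMST curve at fixed covariate values
#'
#' Evaluates the fitted mean model (intercept + time basis + covariate
#' terms) at given covariate values; with all covariates 0 this is the
#' baseline RMST curve. Used, e.g., to read off the model-based baseline
#' RMST at a restriction time of interest.
#'
#' @inheritParams difference_curve
#' @param covariates named list of covariate values; unnamed covariates
#'   default to 0 (the reference coding).
#' @return data.frame with \code{time}, \code{estimate}, \code{se}
#'   (robust).
#' @export
rmst_curve_at <- function(fit, eval_times = NULL, covariates = list(),
                          allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "gee_fit"))
  design <- fit$design
  taus <- design$info$taus
  if (is.null(eval_times)) eval_times <- taus
  rng <- range(taus)
  if (!allow_extrapolation &&
      (any(eval_times < rng[1] - 1e-10) || any(eval_times > rng[2] + 1e-10)))
    stop("evaluation times outside the restriction-time grid")
  B <- basis_eval(design$info, eval_times)
  cols <- design$cols
  C <- matrix(0, length(eval_times), length(cols))
  for (k in seq_along(cols)) {
    cl <- cols[[k]]
    w <- 1
    for (v in cl$covs) w <- w * (if (is.null(covariates[[v]])) 0
                                 else covariates[[v]])
    C[, k] <- if (cl$time == 0L) w else w * B[, cl$time]
  }
  est <- drop(C %*% fit$beta)
  se <- sqrt(pmax(0, rowSums((C %*% fit$robust_cov) * C)))
  data.frame(time = eval_times, estimate = est, se = se)
}

#' Simultaneous confidence band for a difference curve
#'
#' Replaces the pointwise normal quantile by a max-t critical value
#' u_level chosen so that the whole curve is covered with the nominal
#' probability: u_level is the level-quantile of
#' \eqn{\max_t |c(t)'(\beta^* - \hat\beta)| / se(t)} over an equally
#' spaced grid of times on the restriction-time range, with \eqn{\beta^*}
#' drawn from N(\eqn{\hat\beta}, robust covariance). The maximum is
#' computed by Monte Carlo on the standardized contrast scale (correlated
#' standard normals with the contrast correlation matrix), so only the
#' contrast covariance enters. The critical value is floored at the
#' pointwise quantile, hence the band always contains the pointwise
#' interval; for a single grid time the exact normal quantile is used.
#' For dummy-time baselines the band is a step band evaluated at the
#' restriction times themselves.
#'
#' @param fit a \code{\link{fit_gee}} result.
#' @param curve an \code{\link{difference_curve}} result from the same fit.
#' @param level simultaneous coverage level (default 0.95).
#' @param k_grid number of equally spaced grid times used for the supremum
#'   (default 100; ignored for dummy baselines).
#' @param draws Monte-Carlo draws (default 1e5).
#' @param seed integer seed for the draws (default 20220318); the global
#'   RNG state is restored on exit.
#' @return the curve with \code{band_lo}, \code{band_hi} and
#'   \code{u_level} filled in.
#' @export
simultaneous_band <- function(fit, curve, level = 0.95, k_grid = 100L,
                              draws = 1e5, seed = 20220318) {
  stopifnot(inherits(fit, "gee_fit"), inherits(curve, "rmst_curve"),
            level > 0, level < 1, k_grid >= 1)
  taus <- fit$design$info$taus
  grid <- if (fit$design$info$type == "dummy") taus
          else seq(min(taus), max(taus), length.out = k_grid)
  Cg <- contrast_matrix(fit$design, curve$covariate, curve$at, grid)
  V <- fit$robust_cov
  Sigma <- Cg %*% V %*% t(Cg)
  se_g <- sqrt(pmax(0, diag(Sigma)))
  keep <- se_g > 1e-12 * max(se_g, 1e-300)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " grid time(s) with zero variance")
    Sigma <- Sigma[keep, keep, drop = FALSE]
    se_g <- se_g[keep]
  }
  k <- length(se_g)
  z_point <- stats::qnorm((1 + level) / 2)
  u <- if (k <= 1L) z_point else {
    R <- Sigma / tcrossprod(se_g)
    ev <- eigen(R, symmetric = TRUE)
    A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
    chunk <- 20000L
    maxima <- numeric(0)
    remaining <- as.integer(draws)
    while (remaining > 0L) {
      m <- min(chunk, remaining)
      Zm <- matrix(stats::rnorm(m * k), m, k) %*% t(A)
      maxima <- c(maxima, apply(abs(Zm), 1L, max))
      remaining <- remaining - m
    }
    max(z_point, unname(stats::quantile(maxima, level)))
  }
  curve$u_level <- u
  curve$level <- level
  curve$band_lo <- curve$estimate - u * curve$se
  curve$band_hi <- curve$estimate + u * curve$se
  curve
}

#' Does a band cover a true curve everywhere?
#'
#' @param curve an \code{\link{rmst_curve}} with a band (or, lacking one,
#'   its pointwise interval).
#' @param truth a function of time, or a numeric vector matching
#'   \code{curve$eval_times}.
#' @return \code{TRUE} iff lower <= truth <= upper at every evaluation
#'   time (bounds inclusive).
#' @export
covers <- function(curve, truth) {
  stopifnot(inherits(curve, "rmst_curve"))
  tv <- if (is.function(truth)) truth(curve$eval_times) else as.numeric(truth)
  if (length(tv) != length(curve$eval_times))
    stop("truth has wrong length")
  lo <- if (is.null(curve$band_lo)) curve$ci_lo else curve$band_lo
  hi <- if (is.null(curve$band_hi)) curve$ci_hi else curve$band_hi
  all(lo <= tv & tv <= hi)
}

#' @export
as.data.frame.rmst_curve <- function(x, ...) {
  out <- data.frame(time = x$eval_times, estimate = x$estimate, se = x$se,
                    ci_lo = x$ci_lo, ci_hi = x$ci_hi)
  if (!is.null(x$band_lo)) {
    out$band_lo <- x$band_lo
    out$band_hi <- x$band_hi
    out$u <- x$u_level
  }
  out
}

#' @export
print.rmst_curve <- function(x, ...) {
  cat(sprintf("<rmst_curve> D(t) for '%s' at %d times%s\n", x$covariate,
              length(x$eval_times),
              if (!is.null(x$u_level))
                sprintf("; %.0f%% simultaneous band (u = %.3f)",
                        100 * x$level, x$u_level) else ""))
  print(head(as.data.frame(x), 8L))
  if (length(x$eval_times) > 8L) cat("...\n")
  invisible(x)
}

#' Plot an RMST difference curve with its confidence band
#'
#' @param x an \code{\link{rmst_curve}}.
#' @param ... passed to \code{plot}.
#' @export
plot.rmst_curve <- function(x, ...) {
  df <- as.data.frame(x)
  ylim <- range(df[setdiff(names(df), c("time", "se", "u"))])
  graphics::plot(df$time, df$estimate, type = "l", lwd = 2,
                 xlab = "time", ylab = "RMST difference", ylim = ylim, ...)
  if (!is.null(x$band_lo))
    graphics::polygon(c(df$time, rev(df$time)),
                      c(df$band_lo, rev(df$band_hi)),
                      col = grDevices::adjustcolor("grey60", 0.4),
                      border = NA)
  graphics::lines(df$time, df$ci_lo, lty = 2)
  graphics::lines(df$time, df$ci_hi, lty = 2)
  graphics::lines(df$time, df$estimate, lwd = 2)
  graphics::abline(h = 0, col = "grey40")
  invisible(x)
}
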