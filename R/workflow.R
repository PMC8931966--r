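#' One-call RMST difference-curve analysis
#'
#' Convenience wrapper chaining the full pipeline on a survival sample:
#' restriction-time grid at event-time quantiles, pseudo-values, data
#' expansion, model fit (dummy-time baseline, fixed-df spline, or
#' QIC-selected spline df), difference curve for one covariate, and its
#' simultaneous confidence band.
#'
#' @param sample a \code{\link{survival_sample}}.
#' @param covariate the covariate whose RMST difference curve is wanted
#'   (must be a column of the sample).
#' @param covariates model covariate terms; defaults to all covariate
#'   columns of the sample.
#' @param at fixed effect-modifier values for the contrast (see
#'   \code{\link{difference_curve}}).
#' @param M,lower_q,upper_q restriction-time grid controls
#'   (\code{\link{choose_time_grid}}).
#' @param baseline \code{"spline"} or \code{"dummy"}.
#' @param df fixed spline df; if \code{NULL} (default) df is selected by
#'   QIC over \code{df_range}.
#' @param df_range QIC search range when \code{df} is NULL.
#' @param time_varying see \code{\link{model_spec}}.
#' @param level,k_grid,draws,band_seed simultaneous-band controls
#'   (\code{\link{simultaneous_band}}).
#' @return list with \code{grid}, \code{pv}, \code{fit}, \code{qic_trace}
#'   (NULL unless df was selected), and \code{curve} (with band).
#' @examples
#' sc <- builtin_scenario(3)
#' s <- simulate_sample(sc, 300, seed = 7)
#' res <- fit_rmst_curve(s, "Z", df_range = 4:6, draws = 5e3)
#' head(as.data.frame(res$curve))
#' @export
fit_rmst_curve <- function(sample, covariate, covariates = NULL, at = list(),
                           M = 16L, lower_q = 0.01, upper_q = 0.99,
                           baseline = "spline", df = NULL, df_range = 3:12,
                           time_varying = "all", level = 0.95,
                           k_grid = 100L, draws = 1e5, band_seed = 20220318) {
  stopifnot(inherits(sample, "survival_sample"))
  if (is.null(covariates)) covariates <- covariate_names(sample)
  if (!covariate %in% unlist(strsplit(covariates, ":")))
    stop("contrast covariate '", covariate, "' is not in the model terms")
  grid <- choose_time_grid(sample, M = M, lower_q = lower_q,
                           upper_q = upper_q)
  pv <- pseudo_values(sample, grid)
  long <- expand_data(pv, sample)
  qic_trace <- NULL
  if (baseline == "dummy") {
    fit <- fit_gee(long, build_design(
      model_spec("dummy", covariates = covariates,
                 time_varying = time_varying), long))
  } else if (!is.null(df)) {
    fit <- fit_gee(long, build_design(
      model_spec("spline", df = df, covariates = covariates,
                 time_varying = time_varying), long))
  } else {
    sel <- select_spline_df(long, model_spec("spline", df = min(df_range),
                                             covariates = covariates,
                                             time_varying = time_varying),
                            df_range = df_range)
    fit <- sel$fit
    qic_trace <- sel$trace
  }
  curve <- difference_curve(fit, covariate, at = at, level = level)
  curve <- simultaneous_band(fit, curve, level = level, k_grid = k_grid,
                             draws = draws, seed = band_seed)
  list(grid = grid, pv = pv, fit = fit, qic_trace = qic_trace,
       curve = curve)
}
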