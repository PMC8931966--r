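#' Fit the pseudo-value estimating equations
#'
#' Solves the generalized estimating equations for the expanded
#' pseudo-value data with identity link and independence working
#' correlation. Under that combination the estimating equation is linear,
#' so the coefficients are the ordinary least-squares solution on the
#' expanded data — no iteration is involved. Two covariances are returned:
#' \describe{
#'   \item{naive ("model-based")}{\eqn{\hat\phi (Z'Z)^{-1}} with dispersion
#'     \eqn{\hat\phi = RSS/(N-p)}, what GEE software reports as the
#'     independence model-based variance;}
#'   \item{robust (sandwich)}{\eqn{(Z'Z)^{-1}\big[\sum_i U_i U_i'\big]
#'     (Z'Z)^{-1}} with the score contributions \eqn{U_i = Z_i' r_i}
#'     summed within subject (cluster = subject), valid under
#'     working-correlation misspecification. For pseudo-values it is known
#'     to be slightly conservative; no correction is applied.}
#' }
#'
#' @param long the expanded table from \code{\link{expand_data}} (must
#'   contain \code{id} and \code{pseudo_value}).
#' @param design an \code{\link{build_design}} object on the same rows.
#' @return an object of class \code{"gee_fit"} with \code{beta},
#'   \code{naive_cov}, \code{robust_cov}, \code{residual_ss},
#'   \code{n_subjects}, \code{n_obs}, and the design.
#' @export
fit_gee <- function(long, design) {
  stopifnot(is.data.frame(long), inherits(design, "rmst_design"))
  X <- design$X
  y <- long$pseudo_value
  id <- long$id
  if (nrow(X) != length(y)) stop("design and data have different row counts")
  if (length(unique(id)) < 2L)
    stop("at least 2 subjects are required (sandwich variance undefined)")
  p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) stop("singular normal equations")
  beta <- fit$coefficients
  res <- fit$residuals
  XtX_inv <- chol2inv(chol(crossprod(X)))
  rss <- sum(res^2)
  phi <- rss / (length(y) - p)
  naive <- phi * XtX_inv
  # cluster (subject) score sums: U_i = sum_j Z_ij * r_ij
  U <- rowsum(X * res, group = id)
  meat <- crossprod(U)
  robust <- XtX_inv %*% meat %*% XtX_inv
  dimnames(naive) <- dimnames(robust) <- list(colnames(X), colnames(X))
  structure(list(beta = beta, naive_cov = naive, robust_cov = robust,
                 residual_ss = rss, dispersion = phi,
                 n_subjects = length(unique(id)), n_obs = length(y),
                 design = design),
            class = "gee_fit")
}

#' @export
coef.gee_fit <- function(object, ...) object$beta

#' @export
vcov.gee_fit <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$robust_cov else object$naive_cov
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("<gee_fit> %d subjects, %d rows, %d coefficients (identity link, independence)\n",
              x$n_subjects, x$n_obs, length(x$beta)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, ...) {
  se_r <- sqrt(pmax(0, diag(object$robust_cov)))
  se_n <- sqrt(pmax(0, diag(object$naive_cov)))
  data.frame(term = names(object$beta), estimate = unname(object$beta),
             robust_se = unname(se_r), naive_se = unname(se_n),
             row.names = NULL)
}

#' Quasi-information criterion for pseudo-value GEE fits
#'
#' Computes \deqn{QIC = SS + 2\,\mathrm{tr}(N^{-1} V)} where SS is the
#' residual sum of squares of the pseudo-value fit (the quadratic
#' quasi-likelihood kernel, QL = -SS/2, so that lower QIC means better
#' fit), N the naive covariance and V the robust covariance. When models
#' sharing the independence working correlation are compared, the trace
#' penalty may be replaced by twice the number of parameters
#' (\code{penalty = "2p"}).
#'
#' @param fit a \code{\link{fit_gee}} result.
#' @param penalty \code{"trace"} (default) for 2 tr(N^-1 V), or
#'   \code{"2p"} for 2 * number of coefficients.
#' @return the QIC value (lower is better).
#' @export
qic <- function(fit, penalty = c("trace", "2p")) {
  stopifnot(inherits(fit, "gee_fit"))
  penalty <- match.arg(penalty)
  pen <- if (penalty == "trace") {
    tr <- sum(diag(solve(fit$naive_cov, fit$robust_cov)))
    2 * tr
  } else 2 * length(fit$beta)
  fit$residual_ss + pen
}

#' Select the spline dimension by QIC
#'
#' Fits the model for each candidate spline df and returns the fit with
#' the smallest QIC; ties break toward the smaller df. Candidates whose
#' design is rank deficient on the grid (df too large for the number of
#' restriction times) are skipped.
#'
#' @param long expanded table from \code{\link{expand_data}}.
#' @param spec a spline \code{\link{model_spec}} used as template (its
#'   \code{df} is overridden).
#' @param df_range integer vector of candidate df values (default 3:12).
#' @param penalty passed to \code{\link{qic}}.
#' @return list with \code{best_df}, \code{fit} (the winning
#'   \code{gee_fit}), and \code{trace} (data.frame of df and QIC).
#' @export
select_spline_df <- function(long, spec, df_range = 3:12,
                             penalty = "trace") {
  stopifnot(inherits(spec, "model_spec"), length(df_range) >= 1)
  if (spec$baseline != "spline")
    stop("df selection applies to spline baselines only")
  fits <- list()
  qics <- rep(NA_real_, length(df_range))
  for (k in seq_along(df_range)) {
    cand <- spec
    cand$df <- as.integer(df_range[k])
    fit_k <- tryCatch(fit_gee(long, build_design(cand, long)),
                      error = function(e) NULL)
    if (!is.null(fit_k)) {
      fits[[k]] <- fit_k
      qics[k] <- qic(fit_k, penalty = penalty)
    }
  }
  if (all(is.na(qics))) stop("no candidate spline df produced a valid fit")
  best <- which.min(qics)   # which.min takes the first (smallest df) on ties
  list(best_df = as.integer(df_range[best]), fit = fits[[best]],
       trace = data.frame(df = df_range, qic = qics))
}
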