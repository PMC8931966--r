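#' Regression model specification for pseudo-value RMST models
#'
#' Describes the mean model fitted to the expanded (subject x restriction
#' time) pseudo-value data with an identity link:
#' a baseline RMST curve in time (either a saturated set of restriction-time
#' indicators or a natural cubic spline), covariate main effects, and
#' time-varying effects as interactions between the time basis and the
#' covariates. Because the identity link makes covariate coefficients RMST
#' differences, a time-constant difference is rarely plausible; by default
#' every covariate term therefore also gets time interactions
#' (\code{time_varying = "all"}).
#'
#' @param baseline \code{"spline"} (natural cubic spline in time) or
#'   \code{"dummy"} (one indicator per restriction time beyond the first).
#' @param df spline degrees of freedom (number of basis columns), required
#'   for the spline baseline; ignored for dummy.
#' @param covariates character vector of covariate terms; products are
#'   written \code{"A:B"} (e.g. \code{c("Asc", "A", "Age", "Asc:A")}).
#' @param time_varying \code{"all"} (default), or a character subset of
#'   \code{covariates} that get time interactions (others keep a
#'   time-constant effect).
#' @return an object of class \code{"model_spec"}.
#' @export
model_spec <- function(baseline = c("spline", "dummy"), df = NULL,
                       covariates = character(0), time_varying = "all") {
  baseline <- match.arg(baseline)
  if (baseline == "spline") {
    if (is.null(df) || df < 1) stop("spline baseline requires df >= 1")
    df <- as.integer(df)
  }
  covariates <- as.character(covariates)
  if (!identical(time_varying, "all")) {
    extra <- setdiff(time_varying, covariates)
    if (length(extra))
      stop("time_varying terms not among covariates: ",
           paste(extra, collapse = ", "))
  }
  structure(list(baseline = baseline, df = df, covariates = covariates,
                 time_varying = time_varying, link = "identity"),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> baseline = %s%s; covariates: %s; time-varying: %s\n",
              x$baseline,
              if (x$baseline == "spline") sprintf("(df=%d)", x$df) else "",
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "none",
              paste(x$time_varying, collapse = ", ")))
  invisible(x)
}

#' Expand a sample and its pseudo-values to long format
#'
#' Builds the n*M-row regression table: one row per subject and
#' restriction time, with the pseudo-value as response and the subject's
#' covariates replicated across its M rows. The subject id is kept for
#' cluster-robust variance estimation.
#'
#' @param pv a \code{\link{pseudo_values}} result.
#' @param sample the \code{\link{survival_sample}} the pseudo-values were
#'   computed from.
#' @return a data.frame with columns \code{id}, \code{tau},
#'   \code{pseudo_value}, then covariates; attribute \code{"taus"} carries
#'   the restriction-time grid.
#' @export
expand_data <- function(pv, sample) {
  stopifnot(inherits(pv, "pseudo_value_set"),
            inherits(sample, "survival_sample"))
  if (nrow(sample) != pv$source_n)
    stop("sample and pseudo-value set have different numbers of subjects")
  long <- pseudo_long(pv)
  cn <- covariate_names(sample)
  for (v in cn) long[[v]] <- rep(sample[[v]], times = length(pv$taus))
  attr(long, "taus") <- pv$taus
  long
}

# interior knots at equally spaced quantiles of the grid times, boundary
# knots at the grid extremes
spline_basis_info <- function(taus, df) {
  if (df > length(taus) - 1L)
    stop("spline df too large for ", length(taus), " grid times")
  boundary <- range(taus)
  knots <- if (df >= 2L)
    unname(stats::quantile(taus, probs = seq_len(df - 1L) / df))
  else numeric(0)
  list(df = df, interior_knots = knots, boundary_knots = boundary)
}

# evaluate the time basis at times t: matrix length(t) x (df or M-1).
# Natural cubic spline columns extrapolate linearly beyond the boundary
# knots; dummy columns are indicators matched to the grid times.
basis_eval <- function(info, t) {
  if (info$type == "spline") {
    b <- info$basis
    unclass(splines::ns(t, knots = b$interior_knots,
                        Boundary.knots = b$boundary_knots))
  } else {
    taus <- info$taus
    out <- matrix(0, length(t), length(taus) - 1L)
    idx <- vapply(t, function(tt) {
      k <- which(abs(taus - tt) <= 1e-8 * max(1, abs(tt)))
      if (!length(k)) stop("dummy-time model can only be evaluated at its ",
                           "restriction times")
      k
    }, integer(1))
    for (r in seq_along(t)) if (idx[r] > 1L) out[r, idx[r] - 1L] <- 1
    out
  }
}

#' Build the design matrix on the expanded data
#'
#' Assembles the model matrix for a \code{\link{model_spec}} on the long
#' table from \code{\link{expand_data}}: intercept; time basis columns
#' (M-1 restriction-time indicators or df natural-spline columns, interior
#' knots at equally spaced quantiles of the grid, boundary knots at the
#' grid extremes); one main-effect column per covariate term; and, for
#' each time-varying term, its products with every time-basis column.
#' Column metadata records which covariates and which time-basis column
#' each coefficient involves, so difference-curve contrasts can be
#' assembled later.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param long a table from \code{\link{expand_data}}.
#' @return an object of class \code{"rmst_design"}: list with the model
#'   matrix \code{X}, column metadata \code{cols}, the basis description
#'   \code{info}, and \code{spec}.
#' @examples
#' s <- survival_sample(c(1, 2, 3, 4, 6, 7), c(1, 1, 0, 1, 1, 1),
#'                      data.frame(A = c(0, 1, 0, 1, 0, 1)))
#' pv <- pseudo_values(s, taus = c(1, 2, 4, 6))
#' d <- build_design(model_spec("dummy", covariates = "A"),
#'                   expand_data(pv, s))
#' colnames(d$X)   # 1, I(t2..t4), A, I(t2..t4):A  -> 8 columns
#' @export
build_design <- function(spec, long) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(long))
  taus <- attr(long, "taus")
  if (is.null(taus)) taus <- sort(unique(long$tau))
  info <- if (spec$baseline == "spline") {
    c(list(type = "spline", taus = taus),
      list(basis = spline_basis_info(taus, spec$df)))
  } else list(type = "dummy", taus = taus)
  B <- basis_eval(info, long$tau)
  nb <- ncol(B)
  bnames <- if (info$type == "spline") paste0("b", seq_len(nb), "(t)")
            else paste0("I(t", seq_len(nb) + 1L, ")")

  # resolve a covariate term (possibly "A:B") to its column vector
  term_value <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    missing_cov <- setdiff(parts, names(long))
    if (length(missing_cov))
      stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
    Reduce(`*`, long[parts])
  }

  cols <- list(list(label = "(Intercept)", covs = character(0), time = 0L))
  Xlist <- list(rep(1, nrow(long)))
  for (j in seq_len(nb)) {
    cols[[length(cols) + 1L]] <- list(label = bnames[j],
                                      covs = character(0), time = j)
    Xlist[[length(Xlist) + 1L]] <- B[, j]
  }
  tv <- if (identical(spec$time_varying, "all")) spec$covariates
        else spec$time_varying
  for (term in spec$covariates) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    v <- term_value(term)
    cols[[length(cols) + 1L]] <- list(label = term, covs = parts, time = 0L)
    Xlist[[length(Xlist) + 1L]] <- v
    if (term %in% tv) {
      for (j in seq_len(nb)) {
        cols[[length(cols) + 1L]] <-
          list(label = paste0(bnames[j], ":", term), covs = parts, time = j)
        Xlist[[length(Xlist) + 1L]] <- B[, j] * v
      }
    }
  }
  X <- do.call(cbind, Xlist)
  colnames(X) <- vapply(cols, `[[`, character(1), "label")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  structure(list(X = X, cols = cols, info = info, spec = spec),
            class = "rmst_design")
}

#' @export
print.rmst_design <- function(x, ...) {
  cat(sprintf("<rmst_design> %d rows x %d columns (%s baseline, %d grid times)\n",
              nrow(x$X), ncol(x$X), x$info$type, length(x$info$taus)))
  invisible(x)
}
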