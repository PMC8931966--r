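#' Construct a right-censored survival sample
#'
#' The core data container: one row per subject with follow-up time,
#' event indicator and optional numeric covariates. All downstream
#' machinery (Kaplan-Meier, pseudo-values, GEE) consumes this class.
#'
#' @param time non-negative follow-up times.
#' @param event event indicators, 1 = event observed, 0 = right-censored.
#' @param covariates optional data.frame (or NULL) of numeric covariate
#'   columns, one row per subject, no missing values.
#' @return an object of class \code{"survival_sample"}: a data.frame with
#'   columns \code{time}, \code{event} and the covariates.
#' @examples
#' survival_sample(c(1, 2, 4), c(1, 1, 1))
#' @export
survival_sample <- function(time, event, covariates = NULL) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  n <- length(time)
  if (n < 2L) stop("a survival sample needs at least 2 subjects")
  if (length(event) != n) stop("`time` and `event` lengths differ")
  bad <- which(!is.finite(time) | time < 0)
  if (length(bad))
    stop("negative or non-finite time at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  bad <- which(!event %in% c(0, 1))
  if (length(bad))
    stop("event indicator not in {0, 1} at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per subject")
    if (anyNA(covariates)) stop("covariates contain missing values")
    if (!all(vapply(covariates, is.numeric, logical(1))))
      stop("all covariate columns must be numeric")
    if (any(c("time", "event") %in% names(covariates)))
      stop("covariate columns may not be named 'time' or 'event'")
  } else {
    covariates <- data.frame(row.names = seq_len(n))
  }
  out <- cbind(data.frame(time = time, event = event), covariates)
  class(out) <- c("survival_sample", "data.frame")
  out
}

#' @export
print.survival_sample <- function(x, ...) {
  cat(sprintf("<survival_sample> n = %d, events = %d (%.1f%%), covariates: %s\n",
              nrow(x), sum(x$event), 100 * mean(x$event),
              if (ncol(x) > 2L) paste(names(x)[-(1:2)], collapse = ", ")
              else "none"))
  invisible(x)
}

#' Covariate column names of a sample
#' @param sample a \code{\link{survival_sample}}.
#' @return character vector (possibly empty).
#' @export
covariate_names <- function(sample) {
  stopifnot(inherits(sample, "survival_sample"))
  setdiff(names(sample), c("time", "event"))
}

#' Read a survival sample from delimited text
#'
#' Reads a CSV or TSV file with a header row and validates it into a
#' \code{\link{survival_sample}}. Columns other than the named ones are
#' ignored. The delimiter is sniffed from the header line unless given.
#'
#' @param path file path.
#' @param time_col,event_col names of the follow-up-time and event columns.
#' @param covariate_cols character vector of covariate column names
#'   (default none).
#' @param sep field delimiter; \code{NULL} (default) sniffs "," vs tab.
#' @return a \code{\link{survival_sample}}; row order preserved.
#' @export
read_survival_sample <- function(path, time_col = "time",
                                 event_col = "event",
                                 covariate_cols = character(0),
                                 sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(time_col, event_col, covariate_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  cov <- if (length(covariate_cols)) df[covariate_cols] else NULL
  survival_sample(df[[time_col]], df[[event_col]], cov)
}
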