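#' Construct a survival dataset
#'
#' Bundles right-censored follow-up data in the form used throughout the
#' package: one row per subject with an observed time, an event indicator
#' and a numeric covariate matrix.
#'
#' @param time Positive follow-up times, one per subject (arbitrary units).
#' @param status Event indicators: 1 for an observed event (death), 0 for a
#'   censored observation.
#' @param covariates Numeric matrix with one row per subject and one column
#'   per feature; no missing values are allowed.
#' @param feature_names Optional character vector of feature identifiers
#'   (length `ncol(covariates)`); defaults to existing column names or
#'   `x1..xp`.
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `time`, `status`, `covariates` (with column names set), `n` and `p`.
#' @export
#' @examples
#' d <- survival_dataset(c(2, 5, 3), c(1, 0, 1), matrix(rnorm(6), 3))
#' d$n
survival_dataset <- function(time, status, covariates, feature_names = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (!is.matrix(covariates)) covariates <- matrix(covariates, nrow = length(time))
  storage.mode(covariates) <- "double"
  n <- length(time)
  if (n < 2L) stop("need at least 2 subjects")
  if (length(status) != n || nrow(covariates) != n) {
    stop("time, status and covariates must describe the same subjects")
  }
  if (anyNA(time) || any(time <= 0)) stop("all follow-up times must be positive")
  if (anyNA(status) || !all(status %in% c(0, 1))) stop("status must be 0 (censored) or 1 (event)")
  if (anyNA(covariates)) stop("covariate matrix must not contain missing values")
  p <- ncol(covariates)
  if (p < 1L) stop("need at least one covariate")
  if (is.null(feature_names)) {
    feature_names <- colnames(covariates)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(p))
  }
  if (length(feature_names) != p) stop("feature_names must have length ncol(covariates)")
  colnames(covariates) <- feature_names
  # Precomputed risk-set structure (time order, tie-group bounds, sorted
  # covariates): the partial likelihood and its derivatives are evaluated
  # thousands of times per fit, and the ordering never changes.
  ord <- order(time)
  ts <- time[ord]
  structure(
    list(
      time = time, status = status, covariates = covariates, n = n, p = p,
      sorted = list(
        ord = ord, ts = ts, ss = status[ord],
        first = match(ts, ts),
        last = n + 1L - match(ts, rev(ts)),
        Xs = covariates[ord, , drop = FALSE]
      )
    ),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf(
    "survival_dataset: %d subjects, %d covariates, %d events (%.1f%% censored)\n",
    x$n, x$p, sum(x$status), 100 * mean(x$status == 0)
  ))
  invisible(x)
}

# subset rows (used by cross-validation folds)
subset_subjects <- function(data, idx) {
  survival_dataset(data$time[idx], data$status[idx],
                   data$covariates[idx, , drop = FALSE],
                   colnames(data$covariates))
}
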