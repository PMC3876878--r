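# Tuning-parameter selection by cross-validated partial likelihood (CVPL),
# in the Verweij-van Houwelingen form:
#   CVPL(lambda) = sum_k [ l_full(beta_hat^(-k)) - l_train(-k)(beta_hat^(-k)) ],
# where beta_hat^(-k) is fit with fold k held out, l_full is the partial
# log-likelihood on all subjects and l_train(-k) on the training subjects
# only.  Higher is better.

#' Lambda grid for a penalized Cox path
#'
#' `lambda_max` is the smallest penalty that zeroes every coordinate in one
#' plain-L1 pass from the zero vector (the largest absolute
#' partial-residual gradient of the surrogate linearized at `beta = 0` with
#' unit weights); the grid is `n_lambda` log-spaced values descending from
#' `lambda_max` to `ratio * lambda_max`.
#'
#' @param data A [survival_dataset()].
#' @param n_lambda Number of grid points (default 50).
#' @param ratio Smallest/largest grid value, in (0, 1) (default 0.01).
#' @return A strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_grid <- function(data, n_lambda = 50L, ratio = 0.01) {
  stopifnot(n_lambda >= 2)
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly between 0 and 1")
  surr0 <- linearize(data, rep(0, data$p), dense_limit = 0L)
  lam_max <- 2 * max(abs(surr0$b))
  if (lam_max <= 0) stop("degenerate data: all partial-residual gradients are zero")
  grid <- exp(seq(log(lam_max), log(ratio * lam_max), length.out = n_lambda))
  grid[1] <- lam_max  # exact, so the all-zero guarantee holds at the head
  grid
}

# Stratified fold assignment: event and censored subjects are dealt
# round-robin to K folds after a seeded shuffle, so every fold carries a
# proportional number of events.  Re-randomizes (up to max_tries) if some
# fold's training complement would have no events.
make_folds <- function(status, K, seed, max_tries = 10L) {
  n <- length(status)
  if (K < 2) stop("K must be at least 2")
  if (K > n) stop("more folds than subjects")
  for (try in seq_len(max_tries)) {
    folds <- withr::with_seed(seed + (try - 1L), {
      f <- integer(n)
      for (s in c(1, 0)) {
        idx <- sample(which(status == s))
        if (length(idx)) f[idx] <- rep_len(seq_len(K), length(idx))
      }
      f
    })
    ok <- all(vapply(seq_len(K), function(k) sum(status[folds != k]) > 0, logical(1)))
    if (ok) return(folds)
  }
  stop("could not build folds with at least one event in every training part")
}

#' Cross-validated partial likelihood at one lambda
#'
#' Computes `CVPL(lambda)` (Verweij-van Houwelingen): for each fold the
#' model is fit on the remaining subjects and the fold's contribution is
#' the full-data partial log-likelihood at that fit minus the training-data
#' partial log-likelihood.  Higher is better.
#'
#' @param data A [survival_dataset()].
#' @param method One of `"lasso"`, `"adaptive_lasso"`, `"adaptive_l12"`.
#' @param lam Penalty parameter.
#' @param K Number of folds (default 5).
#' @param seed Integer seed for the stratified fold assignment.
#' @param config A [solver_config()].
#' @param folds Optional precomputed fold assignment (overrides `seed`).
#' @return The scalar CVPL value.
#' @export
cvpl <- function(data, method, lam, K = 5L, seed = 1L,
                 config = solver_config(), folds = NULL) {
  if (is.null(folds)) folds <- make_folds(data$status, K, seed)
  total <- 0
  for (k in sort(unique(folds))) {
    train <- subset_subjects(data, which(folds != k))
    fit <- fit_method(train, method, lam, config)
    total <- total + partial_loglik(data, fit$beta) - partial_loglik(train, fit$beta)
  }
  total
}

#' Select lambda by cross-validated partial likelihood
#'
#' Evaluates CVPL over a [lambda_grid()] and returns the maximizer, with
#' ties broken toward the larger (sparser) lambda.  For the plain Lasso
#' each fold's path is fit with warm starts down the descending grid (the
#' previous lambda's solution seeds the next fit), which is substantially
#' faster than refitting from the all-ones start; the adaptive methods
#' always restart from all ones, because their weights make exact zeros
#' absorbing and a warm start from a sparse solution could never leave it.
#' Set `warm_start = FALSE` to evaluate each lambda independently via
#' [cvpl()].
#'
#' @inheritParams cvpl
#' @param n_lambda,ratio Passed to [lambda_grid()].
#' @param warm_start Warm-start fits along the path (default `TRUE`).
#' @return A list of class `cv_result`: `lam_grid` (descending),
#'   `cvpl_values`, `lam_best`, `fold_assignment`, `seed`, `method`.
#' @export
select_lambda <- function(data, method, K = 5L, seed = 1L,
                          n_lambda = 50L, ratio = 0.01,
                          config = solver_config(), warm_start = TRUE) {
  method <- match.arg(method, solver_methods())
  grid <- lambda_grid(data, n_lambda, ratio)
  folds <- make_folds(data$status, K, seed)
  values <- numeric(length(grid))
  if (warm_start) {
    for (k in sort(unique(folds))) {
      train <- subset_subjects(data, which(folds != k))
      init <- NULL
      lasso_ws <- NULL
      for (i in seq_along(grid)) {
        if (method == "lasso") {
          fit <- fit_method(train, method, grid[i], config, beta_init = init)
          # only the plain Lasso (fixed unit weights) may warm-start from
          # the previous solution: the adaptive weights make exact zeros
          # absorbing, so a warm start from a sparse fit could never grow
          init <- fit$beta
        } else {
          # adaptive fits restart from all ones at every lambda; their
          # second (Lasso-solution) start reuses this fold's warm Lasso path
          lasso_ws <- fit_method(train, "lasso", grid[i], config,
                                 beta_init = lasso_ws)$beta
          fit <- fit_method(train, method, grid[i], config,
                            lasso_init = unname(lasso_ws))
        }
        values[i] <- values[i] +
          partial_loglik(data, fit$beta) - partial_loglik(train, fit$beta)
      }
    }
  } else {
    for (i in seq_along(grid)) {
      values[i] <- cvpl(data, method, grid[i], config = config, folds = folds)
    }
  }
  best <- which.max(values)  # grid is descending: first max = largest lambda
  structure(
    list(lam_grid = grid, cvpl_values = values, lam_best = grid[best],
         fold_assignment = folds, seed = seed, method = method),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s): lambda_best = %g (CVPL = %.4f) over %d grid points\n",
              x$method, x$lam_best, max(x$cvpl_values), length(x$lam_grid)))
  invisible(x)
}
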