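# Cox partial likelihood, derivatives and the Newton linearization that
# turns each step into a penalized least-squares problem.
#
# The negative Hessian of the partial log-likelihood is a sum, over event
# times, of weighted covariance matrices of the covariates within the risk
# set.  Writing pi_ij = w_j 1{j in R_i} / W_i (w_j = exp(eta_j)) it factors
# as
#   -d2 l = X' D X - M' M,
# where D = diag(d), d_j = w_j * sum_{events i: t_i <= t_j} 1 / W_i, and M
# has one row per event holding the risk-set mean mu_i = sum_j pi_ij x_j.
# All internal computations use this factor form, so the p x p matrix is
# never needed for fitting; it is materialized on demand for moderate p.

# linear predictors are clipped here before exponentiation
ETA_CLIP <- 500

# Shared ingredients for likelihood, gradient, Hessian factors and the
# Breslow baseline, evaluated through the dataset's cached time ordering.
# Ties use the Breslow convention: every subject with t_j >= t_i (events
# and censored alike) is in the risk set at t_i.  Returned covariate-shaped
# pieces (d, M) are in ascending time order, matching data$sorted$Xs.
# loglik_only skips the covariate accumulations (cheap path for repeated
# likelihood evaluations during step-halving).
cox_parts <- function(data, beta, loglik_only = FALSE) {
  eta <- drop(data$covariates %*% beta)
  eta <- pmin(pmax(eta, -ETA_CLIP), ETA_CLIP)
  if (anyNA(eta)) stop("NaN/NA in linear predictor; check beta")
  srt <- data$sorted
  res <- cox_parts_cpp(eta[srt$ord], srt$ss, srt$first, srt$last, srt$Xs,
                       !loglik_only)
  for (f in c("grad", "d", "W_ev", "ev")) {
    if (!is.null(res[[f]])) res[[f]] <- drop(res[[f]])
  }
  if (!loglik_only && res$n_events %||% 1L == 0L) {
    res$grad <- numeric(data$p)
    res$d <- numeric(data$n)
    res$M <- matrix(0, 0L, data$p)
    res$ev <- integer(0)
    res$W_ev <- numeric(0)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_beta <- function(beta, p) {
  beta <- as.numeric(beta)
  if (length(beta) != p) stop(sprintf("beta must have length %d", p))
  if (anyNA(beta) || any(!is.finite(beta))) stop("beta must be finite (no NaN/NA)")
  beta
}

#' Risk sets at each event time
#'
#' For every subject with an observed event, returns the indices of the
#' subjects still under observation at that time, `R_i = { j : t_j >= t_i }`
#' (Breslow convention; censored subjects tied with an event time are still
#' at risk at that time).
#'
#' @param time Positive follow-up times.
#' @param status Event indicators (1 event, 0 censored).
#' @return A named list with one integer vector of subject indices per
#'   event, named by the event subject's index.
#' @export
#' @examples
#' risk_sets(c(2, 2, 5), c(1, 0, 1))
risk_sets <- function(time, status) {
  if (length(time) != length(status)) stop("time and status must have equal length")
  if (any(time <= 0)) stop("all times must be positive")
  ev <- which(status == 1)
  if (length(ev) == 0L) stop("no events")
  out <- lapply(ev, function(i) which(time >= time[i]))
  names(out) <- ev
  out
}

#' Cox partial log-likelihood
#'
#' Evaluates `l(beta) = sum_i delta_i { x_i' beta - log sum_{j in R_i}
#' exp(x_j' beta) }` under the Breslow tie convention, with log-sum-exp
#' stabilization (max subtraction) inside the risk-set sums.
#'
#' @param data A [survival_dataset()].
#' @param beta Coefficient vector of length `data$p`.
#' @return The partial log-likelihood (a scalar; `<= 0` at `beta = 0`, and 0
#'   when there are no events).
#' @export
partial_loglik <- function(data, beta) {
  beta <- check_beta(beta, data$p)
  cox_parts(data, beta, loglik_only = TRUE)$loglik
}

#' Gradient and Hessian of the negative partial log-likelihood
#'
#' Follows the convention in which the "gradient" is that of the negative
#' log-likelihood: `grad = -dl/dbeta` and `hessian = -d2l/dbeta dbeta'`.
#' The Hessian is symmetric positive semidefinite (a sum over events of
#' within-risk-set covariance matrices of the covariates).
#'
#' @inheritParams partial_loglik
#' @return A list of class `cox_state` with `beta`, `loglik`, `grad`
#'   (length p) and `hessian` (p x p).  Intended for moderate `p`; the
#'   solvers themselves use [linearize()], which never forms the p x p
#'   matrix.
#' @export
gradient_hessian <- function(data, beta) {
  beta <- check_beta(beta, data$p)
  parts <- cox_parts(data, beta)
  Xs <- data$sorted$Xs
  H <- crossprod(Xs, parts$d * Xs) - crossprod(parts$M)
  H <- (H + t(H)) / 2
  structure(
    list(beta = beta, loglik = parts$loglik, grad = drop(parts$grad),
         hessian = H),
    class = "cox_state"
  )
}

#' Linearize the partial likelihood at a coefficient vector
#'
#' One Newton linearization: the quadratic surrogate
#' `RSS(beta) = beta' H beta - 2 b' beta + const`, with `H` the negative
#' Hessian at the expansion point and `b = H beta_t - grad`.  This is the
#' normal-equation form of the pseudo-data construction (Cholesky
#' square-root design and pseudo-response); the explicit factorization is
#' only possible for full-rank `H`, whereas the normal-equation form is
#' always defined, which is what permits p >> n.
#'
#' The surrogate is stored in factor form (`H = X'DX - M'M`); the dense
#' matrix `H` is attached only when `p <= dense_limit`.
#'
#' @inheritParams partial_loglik
#' @param dense_limit Materialize the dense `H` when `p` is at most this
#'   (default 500).
#' @param with_const Also compute the constant term (via `b' H^- b`, using a
#'   pseudo-inverse when `H` is singular); requires the dense `H`.
#' @return An object of class `cox_surrogate` with elements `b`, `diag`
#'   (the `H_jj = x_j'x_j` of the pseudo-design), `H` (dense or `NULL`),
#'   `const`, `expansion_beta`, and the factors `X`, `d`, `M`.
#' @export
linearize <- function(data, beta, dense_limit = 500L, with_const = FALSE) {
  beta <- check_beta(beta, data$p)
  X <- data$sorted$Xs   # row order is irrelevant to H, b and the sweeps
  parts <- cox_parts(data, beta)
  d <- drop(parts$d)
  M <- parts$M
  hb <- drop(crossprod(X, d * (X %*% beta))) - drop(crossprod(M, M %*% beta))
  b <- hb - drop(parts$grad)
  hdiag <- drop(colSums(X^2 * d)) - drop(colSums(M^2))
  hdiag <- pmax(hdiag, 0)
  H <- NULL
  const <- NA_real_
  if (data$p <= dense_limit) {
    H <- crossprod(X, d * X) - crossprod(M)
    H <- (H + t(H)) / 2
    if (with_const) const <- drop(crossprod(b, pseudo_solve(H, b)))
  } else if (with_const) {
    stop("with_const requires p <= dense_limit")
  }
  structure(
    list(
      b = b, diag = hdiag, H = H, const = const, expansion_beta = beta,
      X = X, d = d, M = M, n = data$n, p = data$p,
      loglik = parts$loglik, grad = parts$grad
    ),
    class = "cox_surrogate"
  )
}

# Minimum-norm solve: ordinary solve when well conditioned, otherwise an
# SVD pseudo-inverse (H from a p >> n fit is singular by construction).
pseudo_solve <- function(H, b) {
  sol <- tryCatch(solve(H, b), error = function(e) NULL)
  if (!is.null(sol)) return(sol)
  sv <- svd(H)
  tol <- max(dim(H)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  sv$v[, pos, drop = FALSE] %*% ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
}

# (H beta)_j for the implicit factor form, given u = X beta and v = M beta
surrogate_hb_j <- function(surr, j, u, v) {
  s <- sum(surr$X[, j] * (surr$d * u))
  if (nrow(surr$M)) s <- s - sum(surr$M[, j] * v)
  s
}

# full H %*% beta without forming H
surrogate_hb <- function(surr, beta) {
  hb <- drop(crossprod(surr$X, surr$d * (surr$X %*% beta)))
  if (nrow(surr$M)) hb <- hb - drop(crossprod(surr$M, surr$M %*% beta))
  hb
}

#' Evaluate the surrogate residual sum of squares
#'
#' `RSS(beta) = beta' H beta - 2 b' beta + const` for a surrogate built by
#' [linearize()] with `with_const = TRUE`.
#'
#' @param surrogate A `cox_surrogate`.
#' @param beta Coefficient vector.
#' @return The RSS value (nonnegative near the expansion point when `H` is
#'   positive semidefinite).
#' @export
surrogate_rss <- function(surrogate, beta) {
  if (is.na(surrogate$const)) stop("surrogate was built without the constant term")
  hb <- surrogate_hb(surrogate, beta)
  drop(sum(beta * hb) - 2 * sum(surrogate$b * beta) + surrogate$const)
}
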