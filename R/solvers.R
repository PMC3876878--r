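# Coordinate "shooting" updates for the L1/2 and (reweighted) L1 penalties
# and the full adaptive L1/2 algorithm with Lasso / adaptive-Lasso
# comparators.
#
# Each outer iteration linearizes the partial likelihood (see linearize())
# and minimizes RSS(beta) + penalty coordinate-wise.  Both update rules are
# soft thresholds on the partial-residual gradient
#   S0_j = dRSS/dbeta_j at (0, beta_{-j}) = 2 * (sum_{k != j} H_jk beta_k - b_j),
# with effective threshold lam*w_j for the L1 rule and lam*w_j/2 for the
# L1/2 rule (the half-power penalty is majorized by |beta| / (2 sqrt(|beta_t|))).

#' Solver configuration
#'
#' @param lam Penalty parameter `lambda >= 0`.
#' @param epsilon Weight stabilizer `eps > 0` added to `|beta_j|` before the
#'   adaptive weights `w_j = (|beta_j| + eps)^(-kappa)` are formed, so that
#'   coefficients that hit zero keep a finite weight.
#' @param tol_inner Max-norm convergence tolerance of the inner (sweep) loop.
#' @param tol_outer Max-norm convergence tolerance of the outer
#'   (relinearization) loop.
#' @param max_inner,max_outer Iteration caps.
#' @param l1_exponent,l12_exponent Weight exponents `kappa` used in the
#'   reweighted-L1 step (default 1, i.e. `w_j = 1/(|beta_j|+eps)`) and in the
#'   L1/2 step (default 1/2, the half-power majorization).
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(lam = 0, epsilon = 1e-2,
                          tol_inner = 1e-4, tol_outer = 1e-4,
                          max_inner = 100L, max_outer = 50L,
                          l1_exponent = 1, l12_exponent = 0.5) {
  stopifnot(lam >= 0, epsilon > 0, tol_inner > 0, tol_outer > 0,
            max_inner >= 1, max_outer >= 1)
  structure(
    list(lam = lam, epsilon = epsilon, tol_inner = tol_inner,
         tol_outer = tol_outer, max_inner = as.integer(max_inner),
         max_outer = as.integer(max_outer), l1_exponent = l1_exponent,
         l12_exponent = l12_exponent),
    class = "solver_config"
  )
}

#' Partial-residual gradient of the surrogate RSS at a zeroed coordinate
#'
#' Returns `S0 = S_j(0, beta_{-j})`, the derivative of
#' `RSS(beta) = beta'H beta - 2 b'beta + c` in coordinate `j`, evaluated with
#' `beta_j` set to 0 and the other coordinates held fixed:
#' `S0 = 2 (sum_{k != j} H_jk beta_k - b_j)`.
#'
#' @param surrogate A `cox_surrogate` from [linearize()].
#' @param beta Current coefficient vector.
#' @param j Coordinate index.
#' @return The scalar `S0`.
#' @export
partial_residual_gradient <- function(surrogate, beta, j) {
  beta <- check_beta(beta, surrogate$p)
  u <- drop(surrogate$X %*% beta)
  v <- if (nrow(surrogate$M)) drop(surrogate$M %*% beta) else numeric(0)
  hb_j <- surrogate_hb_j(surrogate, j, u, v)
  unname(2 * (hb_j - surrogate$diag[j] * beta[j] - surrogate$b[j]))
}

# shared soft-threshold kernel: minimizer of hjj*beta^2 + S0*beta + gamma*|beta|
soft_update <- function(S0, gamma, hjj) {
  if (abs(S0) <= gamma) return(0)
  (sign(S0) * gamma - S0) / (2 * hjj)
}

#' L1/2 shooting coordinate update
#'
#' The coordinate update of the half-power step: returns
#' `(lam*w - 2*S0) / (4*hjj)` if `S0 > lam*w/2`,
#' `(-lam*w - 2*S0) / (4*hjj)` if `S0 < -lam*w/2`, and exactly 0 otherwise —
#' equivalently the minimizer of `hjj*beta^2 + S0*beta + (lam*w/2)*|beta|`.
#'
#' @param S0 Partial-residual gradient at the zeroed coordinate.
#' @param w Adaptive weight `w_j > 0`.
#' @param hjj Diagonal surrogate curvature `x_j'x_j > 0`.
#' @param lam Penalty parameter.
#' @return The updated coefficient (exact 0 when thresholded).
#' @export
l12_shoot_update <- function(S0, w, hjj, lam) {
  if (hjj <= 0) stop("degenerate coordinate")
  stopifnot(w > 0, lam >= 0)
  soft_update(S0, lam * w / 2, hjj)
}

#' L1 shooting coordinate update
#'
#' The (weighted) Lasso coordinate update: returns
#' `(lam*w - S0) / (2*hjj)` if `S0 > lam*w`,
#' `(-lam*w - S0) / (2*hjj)` if `S0 < -lam*w`, and exactly 0 otherwise —
#' the minimizer of `hjj*beta^2 + S0*beta + lam*w*|beta|`.
#'
#' @inheritParams l12_shoot_update
#' @return The updated coefficient (exact 0 when thresholded).
#' @export
l1_shoot_update <- function(S0, w, hjj, lam) {
  if (hjj <= 0) stop("degenerate coordinate")
  stopifnot(w > 0, lam >= 0)
  soft_update(S0, lam * w, hjj)
}

adaptive_weights <- function(beta, epsilon, exponent) {
  (abs(beta) + epsilon)^(-exponent)
}

#' Reweighted L1 shooting pass
#'
#' The inner loop of the adaptive algorithms: cycles through the
#' coordinates applying [l1_shoot_update()] with adaptive weights
#' `w_j = (|beta_j^t| + eps)^(-1)` computed from `weights_source_beta`
#' (the current outer iterate) and held fixed across sweeps — the pass is
#' an exact coordinate-descent solve of the weighted-Lasso objective
#' `RSS(beta) + lam * sum_j |beta_j| / (|beta_j^t| + eps)` — while the
#' partial-residual gradients `S0` refresh at every update.  Sweeps stop
#' when the max-norm change falls below `config$tol_inner` or after
#' `config$max_inner` sweeps.  Passing `fixed_weights` overrides the
#' adaptive weights (the plain Lasso pass uses all ones).
#'
#' @param surrogate A `cox_surrogate`.
#' @param beta_start Starting coefficient vector.
#' @param config A [solver_config()] (supplies `lam`, `epsilon`, tolerances).
#' @param weights_source_beta Coefficients from which the weights are
#'   computed (default `beta_start`).
#' @param fixed_weights Optional positive weights used instead of the
#'   adaptive ones.
#' @return List with `beta`, number of `sweeps`, and a `converged` flag.
#' @export
reweighted_l1_pass <- function(surrogate, beta_start, config,
                               weights_source_beta = beta_start,
                               fixed_weights = NULL) {
  beta <- check_beta(beta_start, surrogate$p)
  w <- if (is.null(fixed_weights)) {
    adaptive_weights(weights_source_beta, config$epsilon, config$l1_exponent)
  } else {
    fixed_weights
  }
  res <- shoot_loop_cpp(surrogate$X, surrogate$M, surrogate$d, surrogate$b,
                        surrogate$diag, beta, config$lam * w,
                        config$tol_inner, config$max_inner)
  list(beta = drop(res$beta), sweeps = res$sweeps, converged = res$converged)
}

#' Single L1/2 shooting pass
#'
#' One cycle of [l12_shoot_update()] over all coordinates with weights
#' `w_j = (|beta_t_j| + eps)^(-1/2)` taken from the expansion iterate
#' `beta_t`, producing the half-power candidate of one outer iteration.
#' Identical to a single reweighted-L1 sweep with penalty `lam/2` and these
#' weights.
#'
#' @inheritParams reweighted_l1_pass
#' @param beta_t The current outer iterate (start point and weight source).
#' @return The updated coefficient vector.
#' @export
l12_pass <- function(surrogate, beta_t, config) {
  beta <- check_beta(beta_t, surrogate$p)
  w <- adaptive_weights(beta_t, config$epsilon, config$l12_exponent)
  res <- shoot_loop_cpp(surrogate$X, surrogate$M, surrogate$d, surrogate$b,
                        surrogate$diag, beta, config$lam * w / 2,
                        config$tol_inner, 1L)
  drop(res$beta)
}

# Penalized objective used for step-halving and the iteration trace: the
# negative partial log-likelihood plus the method's target penalty on the
# RSS scale (RSS tracks 2*(-l) + const, so lambda on RSS corresponds to
# lambda/2 here).  The half-power method monitors its own objective
# sum |beta|^(1/2); the reweighted-L1 pass with weights 1/(|beta^t|+eps)
# is the MM iteration for the log penalty sum log(eps+|beta|), so the
# adaptive Lasso is monitored by that (shifted to vanish at 0); the plain
# Lasso by the L1 norm.
trace_objective <- function(data, beta, lam, method, epsilon = 1e-2,
                            kappa = 1) {
  if (any(!is.finite(beta))) return(Inf)
  pen <- switch(method,
    adaptive_l12 = sum(sqrt(abs(beta))),
    adaptive_lasso = if (kappa == 1) {
      sum(log1p(abs(beta) / epsilon))
    } else {
      # antiderivative of (|beta|+eps)^(-kappa): reduces to the L1 norm at
      # kappa = 0, so forcing unit weights recovers the plain Lasso exactly
      sum(((abs(beta) + epsilon)^(1 - kappa) - epsilon^(1 - kappa)) / (1 - kappa))
    },
    sum(abs(beta))
  )
  -partial_loglik(data, beta) + (lam / 2) * pen
}

fit_penalized_cox <- function(data, lam, config, method, beta_init = NULL,
                              lasso_init = NULL) {
  stopifnot(lam >= 0)
  if (is.null(beta_init) && method != "lasso") {
    # The penalized objective is nonconvex for the adaptive methods and the
    # iteration can settle in a poor basin from the prescribed all-ones
    # start.  Run a second, deterministic start from the plain-Lasso
    # solution at the same lambda (the classical data-adaptive initial
    # estimator) and keep the fit with the lower penalized objective;
    # ties favor the all-ones start.
    fit1 <- fit_penalized_cox_once(data, lam, config, method, NULL)
    lasso_beta <- if (is.null(lasso_init)) {
      fit_penalized_cox_once(data, lam, config, "lasso", NULL)$beta
    } else {
      lasso_init
    }
    fit2 <- fit_penalized_cox_once(data, lam, config, method, unname(lasso_beta))
    o1 <- trace_objective(data, fit1$beta, lam, method, config$epsilon, config$l1_exponent)
    o2 <- trace_objective(data, fit2$beta, lam, method, config$epsilon, config$l1_exponent)
    return(if (o2 < o1) fit2 else fit1)
  }
  fit_penalized_cox_once(data, lam, config, method, beta_init)
}

fit_penalized_cox_once <- function(data, lam, config, method, beta_init = NULL) {
  config$lam <- lam
  p <- data$p
  beta <- if (is.null(beta_init)) rep(1, p) else check_beta(beta_init, p)
  trace <- numeric(0)
  converged <- FALSE
  n_outer <- 0L
  obj_prev <- trace_objective(data, beta, lam, method, config$epsilon, config$l1_exponent)
  best_beta <- beta
  best_obj <- obj_prev
  for (t in seq_len(config$max_outer)) {
    surr <- linearize(data, beta, dense_limit = 0L)
    bnew <- switch(method,
      lasso = reweighted_l1_pass(surr, beta, config,
                                 fixed_weights = rep(1, p))$beta,
      adaptive_lasso = reweighted_l1_pass(surr, beta, config,
                                          weights_source_beta = beta)$beta,
      adaptive_l12 = {
        bstar <- l12_pass(surr, beta, config)
        bm <- reweighted_l1_pass(surr, beta, config,
                                 weights_source_beta = beta)$beta
        # per-coordinate combination: keep the value of smaller magnitude,
        # ties resolved toward the L1/2 candidate
        ifelse(abs(bm) < abs(bstar), bm, bstar)
      },
      stop(sprintf("unknown method '%s'", method))
    )
    # damped Newton safeguard: if the relinearized step overshoots (the
    # monitor objective increases or is non-finite), halve the step toward
    # the previous iterate.  Near a fixed point no halving occurs, so the
    # accepted iterate is a full pass output with exact zeros.
    bad <- !is.finite(bnew)
    if (any(bad)) bnew[bad] <- beta[bad]
    obj <- trace_objective(data, bnew, lam, method, config$epsilon, config$l1_exponent)
    halvings <- 0L
    improved <- function(o) is.finite(o) && o <= obj_prev + 1e-10 * (1 + abs(obj_prev))
    while (!improved(obj) && halvings < 30L) {
      bnew <- (beta + bnew) / 2
      obj <- trace_objective(data, bnew, lam, method, config$epsilon, config$l1_exponent)
      halvings <- halvings + 1L
    }
    n_outer <- t
    if (!improved(obj)) {
      # no step scale improves the monitor: reject and stop at the best
      # iterate seen (the current one, by construction)
      trace <- c(trace, obj_prev)
      break
    }
    trace <- c(trace, obj)
    if (obj < best_obj) {
      best_obj <- obj
      best_beta <- bnew
    }
    delta <- max(abs(bnew - beta))
    beta <- bnew
    obj_prev <- obj
    # genuine convergence: an unhalved full pass that no longer moves the
    # iterate (a damped standstill is not convergence)
    if (delta < config$tol_outer && halvings == 0L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) beta <- best_beta
  names(beta) <- colnames(data$covariates)
  structure(
    list(beta = beta, lam = lam, n_outer = n_outer, converged = converged,
         objective_trace = trace, method = method, config = config),
    class = "cox_l12_fit"
  )
}

#' Fit the adaptive L1/2 shooting regularized Cox model
#'
#' The full five-step algorithm: starting from the all-ones vector, each
#' outer iteration (i) relinearizes the partial likelihood at the current
#' iterate, (ii) takes one L1/2 shooting pass, (iii) runs the reweighted-L1
#' shooting pass to convergence, and (iv) combines the two candidates
#' coordinate-wise by keeping the value of smaller absolute magnitude, until
#' the outer iterate stops changing (max-norm below `config$tol_outer`).
#' Thresholded coordinates are exact zeros.
#'
#' @param data A [survival_dataset()].
#' @param lam Penalty parameter `lambda >= 0`.
#' @param config A [solver_config()]; its `lam` is overridden by `lam`.
#' @param beta_init Optional starting vector (default: all ones, the
#'   algorithm's prescribed start; cross-validation paths warm-start here).
#' @return A `cox_l12_fit` with elements `beta` (named), `lam`, `n_outer`,
#'   `converged`, `objective_trace` (per outer iteration; monitoring only)
#'   and `method`.  On non-convergence the best iterate by the trace
#'   objective is returned with `converged = FALSE`.
#' @export
#' @examples
#' d <- generate_dataset(simulation_config(n = 60, p = 5,
#'   beta_true = c(1, -1, 0, 0, 0), censor_rate = 0), seed = 1)
#' fit <- adaptive_l12_fit(d, lam = 2)
#' fit$beta
adaptive_l12_fit <- function(data, lam, config = solver_config(),
                             beta_init = NULL) {
  fit_penalized_cox(data, lam, config, "adaptive_l12", beta_init)
}

#' Fit the Lasso comparator
#'
#' Same outer linearization loop as [adaptive_l12_fit()] but the inner loop
#' is plain L1 shooting with unit weights (no reweighting, no L1/2 pass, no
#' combination step).
#'
#' @inheritParams adaptive_l12_fit
#' @return A `cox_l12_fit`.
#' @export
lasso_fit <- function(data, lam, config = solver_config(), beta_init = NULL) {
  fit_penalized_cox(data, lam, config, "lasso", beta_init)
}

#' Fit the adaptive Lasso comparator
#'
#' Outer linearization loop with the reweighted-L1 pass only (weights from
#' the previous outer iterate, `w_j = 1/(|beta_j| + eps)`).
#'
#' @inheritParams adaptive_l12_fit
#' @return A `cox_l12_fit`.
#' @export
adaptive_lasso_fit <- function(data, lam, config = solver_config(),
                               beta_init = NULL) {
  fit_penalized_cox(data, lam, config, "adaptive_lasso", beta_init)
}

#' @export
print.cox_l12_fit <- function(x, ...) {
  cat(sprintf(
    "cox_l12_fit (%s): lambda = %g, %d nonzero of %d, %d outer iterations%s\n",
    x$method, x$lam, sum(x$beta != 0), length(x$beta), x$n_outer,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

solver_methods <- function() c("lasso", "adaptive_lasso", "adaptive_l12")

fit_method <- function(data, method, lam, config = solver_config(),
                       beta_init = NULL, lasso_init = NULL) {
  method <- match.arg(method, solver_methods())
  fit_penalized_cox(data, lam, config, method, beta_init, lasso_init)
}
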