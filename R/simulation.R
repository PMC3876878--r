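# Synthetic survival data with a Gompertz baseline hazard
# h0(t) = a * exp(gamma * t) under proportional hazards, plus the
# replication harness for benchmark tables (Var / Corr / Incorr / IBS).

#' Simulation configuration
#'
#' @param n Sample size (>= 10).
#' @param p Number of covariates.
#' @param beta_true True coefficient vector (default [true_beta()] pattern).
#' @param gompertz_a Baseline hazard scale `a > 0` (default 1).
#' @param gompertz_gamma Baseline hazard shape `gamma` (default 0.1;
#'   `gamma = 0` gives an exponential baseline).
#' @param censor_rate Target censoring fraction in `[0, 1)` (default 0.25).
#' @param n_reps Number of benchmark replications (default 100).
#' @param covariate_model `"iid_normal"` (default) or `"ar1"`.
#' @param rho AR(1) correlation when `covariate_model = "ar1"`.
#' @param censor_horizon Optional precomputed upper bound of the uniform
#'   censoring distribution; when `NULL` it is calibrated by
#'   [calibrate_censoring()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n, p, beta_true = true_beta(p),
                              gompertz_a = 1, gompertz_gamma = 0.1,
                              censor_rate = 0.25, n_reps = 100L,
                              covariate_model = c("iid_normal", "ar1"),
                              rho = 0.5, censor_horizon = NULL) {
  covariate_model <- match.arg(covariate_model)
  stopifnot(n >= 10, p >= 1, length(beta_true) == p, gompertz_a > 0,
            censor_rate >= 0, censor_rate < 1, n_reps >= 1)
  structure(
    list(n = as.integer(n), p = as.integer(p), beta_true = as.numeric(beta_true),
         gompertz_a = gompertz_a, gompertz_gamma = gompertz_gamma,
         censor_rate = censor_rate, n_reps = as.integer(n_reps),
         covariate_model = covariate_model, rho = rho,
         censor_horizon = censor_horizon),
    class = "simulation_config"
  )
}

#' Benchmark true coefficient vector
#'
#' The sparse coefficient pattern of the simulation design: the first 14
#' entries are `(-0.7, -0.5, -0.3, -0.1, 0, 0, 0, 0, 0, 0, 0.4, 0, 0, 0.7)`
#' and the remaining `p - 14` entries are 0, giving 6 relevant features
#' (nonzero positions 1, 2, 3, 4, 11, 14) regardless of `p >= 14`.
#'
#' @param p Dimension (default 1000, the design's full scale).
#' @return Numeric vector of length `p`.
#' @export
#' @examples
#' sum(true_beta(1000) != 0)  # 6
true_beta <- function(p = 1000L) {
  if (p < 14) stop("p must be at least 14 to hold the coefficient pattern")
  head14 <- c(-0.7, -0.5, -0.3, -0.1, rep(0, 6), 0.4, 0, 0, 0.7)
  c(head14, rep(0, p - 14))
}

# standard deviation of the linear predictor under the covariate model
eta_sd <- function(config) {
  beta <- config$beta_true
  if (config$covariate_model == "iid_normal") return(sqrt(sum(beta^2)))
  nz <- which(beta != 0)
  if (length(nz) == 0) return(0)
  v <- 0
  for (i in nz) for (j in nz) {
    v <- v + beta[i] * beta[j] * config$rho^abs(i - j)
  }
  sqrt(v)
}

gen_covariates <- function(n, p, model, rho) {
  X <- matrix(stats::rnorm(n * p), n, p)
  if (model == "ar1" && p > 1) {
    for (j in 2:p) X[, j] <- rho * X[, j - 1] + sqrt(1 - rho^2) * X[, j]
  }
  X
}

#' Draw Gompertz proportional-hazards event times
#'
#' Inverse-transform sampling under hazard
#' `h(t | x) = a * exp(gamma * t) * exp(eta)`: with `U ~ Uniform(0, 1)`,
#' `T = log(1 + gamma * (-log U) / (a * exp(eta))) / gamma` for
#' `gamma != 0` and `T = (-log U) / (a * exp(eta))` for `gamma = 0` (the
#' exponential limit).  Uses the current R random-number stream.
#'
#' @param linear_predictor `eta = beta' x` per subject.
#' @param a Baseline scale (`a > 0`).
#' @param gamma Baseline shape.
#' @return Positive event times, one per subject.
#' @export
gen_gompertz_times <- function(linear_predictor, a, gamma) {
  stopifnot(a > 0)
  u <- stats::runif(length(linear_predictor))
  rate <- a * exp(pmin(pmax(linear_predictor, -ETA_CLIP), ETA_CLIP))
  e <- -log(u)
  if (gamma == 0) e / rate else log1p(gamma * e / rate) / gamma
}

#' Calibrate the uniform censoring horizon
#'
#' Censoring times are `C ~ Uniform(0, c)`, independent of the event
#' times.  The horizon `c` is found by bisection so that the Monte-Carlo
#' estimate of `P(C < T)` over `pilot_n` pilot draws of `(x, T)` matches
#' `config$censor_rate` within `tol`.  Given the pilot event times the
#' censoring probability `E[min(T/c, 1)]` is evaluated exactly, and it is
#' monotone decreasing in `c`.  A target rate of 0 returns `Inf` (no
#' censoring).
#'
#' @param config A [simulation_config()].
#' @param pilot_n Number of pilot draws (default 10000).
#' @param tol Calibration tolerance on the rate (default 0.005).
#' @return The censoring horizon `c` (possibly `Inf`).
#' @export
calibrate_censoring <- function(config, pilot_n = 10000L, tol = 0.005) {
  if (config$censor_rate == 0) return(Inf)
  # under the Gaussian covariate models eta = beta'x is exactly
  # N(0, beta' Sigma beta), so the pilot draws eta directly (p-free cost)
  eta <- stats::rnorm(pilot_n, 0, eta_sd(config))
  T_pilot <- gen_gompertz_times(eta, config$gompertz_a, config$gompertz_gamma)
  rate <- function(c) mean(pmin(T_pilot / c, 1))
  lo <- min(T_pilot) / 2
  hi <- max(T_pilot) * 2
  for (i in 1:60) {
    if (rate(lo) >= config$censor_rate) break
    lo <- lo / 10
  }
  for (i in 1:60) {
    if (rate(hi) <= config$censor_rate) break
    hi <- hi * 10
  }
  if (rate(lo) < config$censor_rate || rate(hi) > config$censor_rate) {
    stop("could not bracket the censoring horizon")
  }
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    r <- rate(mid)
    if (abs(r - config$censor_rate) <= tol) return(mid)
    if (r > config$censor_rate) lo <- mid else hi <- mid
  }
  stop("censoring calibration did not converge")
}

#' Generate one synthetic survival dataset
#'
#' Covariates from the configured model (iid standard normal by default),
#' event times from the Gompertz proportional-hazards model, independent
#' `Uniform(0, c)` censoring with `c` calibrated to the target rate;
#' observed time is `min(T, C)` with `delta = 1{T <= C}`.  Fully
#' reproducible from `seed` (the global random-number state is left
#' untouched).
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A [survival_dataset()]; the generating truth is attached as
#'   attributes `beta_true` and `config`.
#' @export
generate_dataset <- function(config, seed) {
  withr::with_seed(seed, {
    horizon <- config$censor_horizon
    if (is.null(horizon)) horizon <- calibrate_censoring(config)
    X <- gen_covariates(config$n, config$p, config$covariate_model, config$rho)
    eta <- drop(X %*% config$beta_true)
    T_ev <- gen_gompertz_times(eta, config$gompertz_a, config$gompertz_gamma)
    C <- if (is.finite(horizon)) stats::runif(config$n, 0, horizon) else rep(Inf, config$n)
    time <- pmin(T_ev, C)
    status <- as.numeric(T_ev <= C)
    out <- survival_dataset(time, status, X)
    attr(out, "beta_true") <- config$beta_true
    attr(out, "config") <- config
    out
  })
}

#' Replicated selection / prediction benchmark
#'
#' For each replication a training set is generated, lambda is selected by
#' K-fold CVPL per method, the model is refit at the selected lambda on the
#' full training set, and the Var / Corr / Incorr selection counts are
#' recorded against the generating coefficients; an independent test set
#' of the same size is generated and the IPCW integrated Brier score of
#' the fitted model is recorded.  Per-method averages and Monte-Carlo
#' standard errors over replications are returned.
#'
#' The pseudo-method `"oracle"` (beta_hat = beta_true, no tuning) is
#' accepted as a harness check.
#'
#' @param config A [simulation_config()] (`n_reps` sets the replication
#'   count).
#' @param methods Character vector of solver ids and/or `"oracle"`.
#' @param K_folds CVPL folds (default 5).
#' @param seed Integer master seed; all replication and fold seeds derive
#'   from it.
#' @param n_lambda,ratio Lambda-grid settings passed to [select_lambda()].
#' @param solver A [solver_config()].
#' @return A `data.frame` of class `cox_l12_benchmark`: one row per method
#'   with columns `var`, `corr`, `incorr`, `ibs`, their `*_se` standard
#'   errors and `n_reps_ok`; the effective configuration is attached as
#'   attribute `config`.
#' @export
run_benchmark <- function(config, methods = solver_methods(), K_folds = 5L,
                          seed = 1L, n_lambda = 50L, ratio = 0.01,
                          solver = solver_config()) {
  n_reps <- config$n_reps
  sub_seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1L, 3L * n_reps), nrow = n_reps)
  })
  if (is.null(config$censor_horizon)) {
    config$censor_horizon <- withr::with_seed(seed, calibrate_censoring(config))
  }
  recs <- list()
  failures <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      train <- generate_dataset(config, seed = sub_seeds[r, 1])
      test <- generate_dataset(config, seed = sub_seeds[r, 2])
      rows <- lapply(methods, function(m) {
        if (m == "oracle") {
          beta_hat <- config$beta_true
          lam <- NA_real_
        } else {
          sel <- select_lambda(train, m, K = K_folds, seed = sub_seeds[r, 3],
                               n_lambda = n_lambda, ratio = ratio, config = solver)
          fit <- fit_method(train, m, sel$lam_best, solver)
          beta_hat <- fit$beta
          lam <- sel$lam_best
        }
        sm <- selection_metrics(beta_hat, config$beta_true)
        ibs <- integrated_brier_score(train, test, beta_hat)
        data.frame(method = m, rep = r, lam = lam, var = sm$var_count,
                   corr = sm$corr_zeros, incorr = sm$incorr_zeros, ibs = ibs)
      })
      do.call(rbind, rows)
    }, error = function(e) {
      warning(sprintf("replication %d failed: %s", r, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else recs[[length(recs) + 1L]] <- res
  }
  if (failures > 0.2 * n_reps) stop("more than 20% of replications failed")
  per_rep <- do.call(rbind, recs)
  agg <- lapply(methods, function(m) {
    sub <- per_rep[per_rep$method == m, ]
    se <- function(x) stats::sd(x) / sqrt(length(x))
    data.frame(
      method = m, var = mean(sub$var), corr = mean(sub$corr),
      incorr = mean(sub$incorr), ibs = mean(sub$ibs),
      var_se = se(sub$var), corr_se = se(sub$corr),
      incorr_se = se(sub$incorr), ibs_se = se(sub$ibs),
      n_reps_ok = nrow(sub)
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  attr(out, "per_rep") <- per_rep
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("cox_l12_benchmark", class(out))
  out
}
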