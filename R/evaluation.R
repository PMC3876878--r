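# Prediction and selection metrics: risk scores, risk-group split,
# Kaplan-Meier curves, log-rank test, Breslow baseline hazard and the IPCW
# integrated Brier score, plus the Var/Corr/Incorr selection counts.

#' Linear risk scores
#'
#' `f(x) = beta' x` for each subject; higher scores mean higher hazard.
#'
#' @param beta Coefficient vector.
#' @param covariates Matrix with one row per subject.
#' @return Numeric vector of scores.
#' @export
risk_score <- function(beta, covariates) {
  if (!is.matrix(covariates)) covariates <- matrix(covariates, ncol = length(beta))
  drop(covariates %*% beta)
}

#' Split subjects into risk groups at a score cutoff
#'
#' Label 1 (high risk) iff `score > cutoff`; scores exactly at the cutoff
#' go to the low-risk group.
#'
#' @param scores Numeric risk scores.
#' @param cutoff Cut point (default 0, the convention for centered linear
#'   predictors).
#' @return Integer labels (0 = low risk, 1 = high risk).
#' @export
split_groups <- function(scores, cutoff = 0) {
  as.integer(scores > cutoff)
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct event times,
#' computed via [survival::survfit()].
#'
#' @param time Positive follow-up times.
#' @param status Event indicators.
#' @return A list of class `km_curve`: `grid_times` (sorted distinct event
#'   times), `survival`, `at_risk`, `events`.  With no events the grid is
#'   empty and the curve is identically 1.
#' @export
km_estimator <- function(time, status) {
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  keep <- sf$n.event > 0
  structure(
    list(grid_times = sf$time[keep], survival = sf$surv[keep],
         at_risk = sf$n.risk[keep], events = sf$n.event[keep]),
    class = "km_curve"
  )
}

#' Evaluate a Kaplan-Meier curve as a step function
#'
#' Right-continuous evaluation; `left = TRUE` gives the left limit
#' `S(t-)` used by the IPCW event-term weights.  `S = 1` before the first
#' event time.
#'
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate.
#' @param left Evaluate the left limit instead.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival <- function(curve, t, left = FALSE) {
  if (length(curve$grid_times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, curve$grid_times, left.open = left)
  c(1, curve$survival)[idx + 1L]
}

#' Two-group log-rank test
#'
#' Chi-square log-rank statistic (1 df) via [survival::survdiff()], with
#' the p-value from the upper chi-square tail; lower p indicates a clearer
#' separation of the survival curves.
#'
#' @param time Positive follow-up times.
#' @param status Event indicators.
#' @param groups Two-level group labels.
#' @return List with `statistic` and `p_value`.
#' @export
logrank_test <- function(time, status, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("exactly two groups are required")
  sd <- survival::survdiff(survival::Surv(time, status) ~ groups)
  stat <- sd$chisq
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Breslow baseline survival
#'
#' The Breslow step estimator of the cumulative baseline hazard at fitted
#' coefficients `beta`:
#' `H0(t) = sum_{t_i <= t} d_i / sum_{j in R_i} exp(x_j' beta)`, with
#' `S0(t) = exp(-H0(t))`.  Subject-level predictions are
#' `S(t | x) = S0(t)^exp(beta' x)` (see [predict_survival()]).  At
#' `beta = 0` this is the Nelson-Aalen estimator.
#'
#' @param data Training [survival_dataset()].
#' @param beta Coefficient vector.
#' @return List of class `baseline_survival`: `times` (distinct event
#'   times), `cumhaz`, `survival`.
#' @export
baseline_survival <- function(data, beta) {
  beta <- check_beta(beta, data$p)
  parts <- cox_parts(data, beta)
  ev <- drop(parts$ev)
  if (length(ev) == 0L) {
    return(structure(list(times = numeric(0), cumhaz = numeric(0),
                          survival = numeric(0)), class = "baseline_survival"))
  }
  event_times <- data$sorted$ts[ev]
  ut <- unique(event_times)  # sorted ascending
  dk <- as.numeric(table(factor(event_times, levels = ut)))
  Wk <- drop(parts$W_ev)[match(ut, event_times)] * exp(parts$log_shift)
  cumhaz <- cumsum(dk / Wk)
  structure(list(times = ut, cumhaz = cumhaz, survival = exp(-cumhaz)),
            class = "baseline_survival")
}

#' Predicted survival probabilities from a fitted linear predictor
#'
#' `S(t | x) = S0(t)^exp(beta' x)` with `S0` the Breslow baseline estimated
#' on the training data.
#'
#' @param train Training [survival_dataset()].
#' @param beta Coefficient vector.
#' @param newdata Covariate matrix of the subjects to predict (one row per
#'   subject).
#' @param times Evaluation times.
#' @return Matrix of survival probabilities, subjects x times.
#' @export
predict_survival <- function(train, beta, newdata, times) {
  base <- baseline_survival(train, beta)
  H0 <- c(0, base$cumhaz)[findInterval(times, base$times) + 1L]
  eta <- risk_score(beta, newdata)
  eta <- pmin(pmax(eta, -ETA_CLIP), ETA_CLIP)
  exp(-outer(exp(eta), H0))
}

# Graf-style IPCW Brier scores at the given evaluation times.
# surv_pred: subjects x times matrix of predicted S(t | x_i).
# Gfun(t, left): censoring-survival evaluator (from the training KM).
brier_scores <- function(time, status, surv_pred, eval_times, Gfun) {
  n <- length(time)
  G_left <- Gfun(time, left = TRUE)
  vapply(seq_along(eval_times), function(k) {
    t <- eval_times[k]
    S <- surv_pred[, k]
    Gt <- Gfun(t, left = FALSE)
    w_event <- as.numeric(time <= t & status == 1) / G_left
    w_alive <- as.numeric(time > t) / Gt
    w_event[!is.finite(w_event)] <- 0
    w_alive[!is.finite(w_alive)] <- 0
    sum(w_event * (0 - S)^2 + w_alive * (1 - S)^2) / n
  }, numeric(1))
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Integrated Brier score from a prediction matrix
#'
#' Time-averaged IPCW (Graf) Brier score: `BS(t)` is integrated over
#' `[0, t_max]` by the trapezoid rule on the supplied grid and divided by
#' `t_max`.  This is the computational core of
#' [integrated_brier_score()]; it takes an arbitrary prediction matrix so
#' that oracle or constant predictors can be scored directly.
#'
#' @param time,status Test-set follow-up data.
#' @param surv_pred Subjects x times matrix of predicted survival
#'   probabilities at `eval_times`.
#' @param eval_times Grid over `[0, t_max]`; must start at 0.
#' @param censor_km `km_curve` of the censoring distribution (typically fit
#'   on training data); `NULL` means no censoring (weights 1).
#' @return The IBS value.
#' @export
ibs_from_predictions <- function(time, status, surv_pred, eval_times,
                                 censor_km = NULL) {
  stopifnot(length(eval_times) >= 2, eval_times[1] == 0)
  Gfun <- if (is.null(censor_km)) {
    function(t, left = FALSE) rep(1, length(t))
  } else {
    function(t, left = FALSE) km_survival(censor_km, t, left = left)
  }
  bs <- brier_scores(time, status, surv_pred, eval_times, Gfun)
  t_max <- eval_times[length(eval_times)]
  trapezoid(eval_times, bs) / t_max
}

#' Integrated Brier score of a fitted Cox model on a test set
#'
#' Predictions `S(t | x)` come from the Breslow baseline and linear
#' predictor estimated on the training data; the censoring distribution
#' `G` is the Kaplan-Meier estimator of censoring on the training data
#' (left limits for the event terms), so nothing is estimated from the
#' test set.  `BS(t)` is evaluated on the grid of distinct test event
#' times up to `t_max` (plus the endpoints 0 and `t_max`) and integrated
#' by the trapezoid rule.  If `G` reaches 0 before `t_max`, `t_max` is
#' truncated to the last usable time with a warning.
#'
#' @param train Training [survival_dataset()].
#' @param test Test [survival_dataset()].
#' @param beta Fitted coefficient vector.
#' @param t_max Upper limit of integration; defaults to the 95th percentile
#'   of test follow-up times, and must not exceed the largest test time.
#' @return The IBS value.
#' @export
integrated_brier_score <- function(train, test, beta,
                                   t_max = stats::quantile(test$time, 0.95, names = FALSE)) {
  if (t_max > max(test$time)) stop("t_max must not exceed the largest test follow-up time")
  G <- km_estimator(train$time, 1 - train$status)
  if (length(G$grid_times) && any(G$survival <= 0)) {
    g_zero <- min(G$grid_times[G$survival <= 0])
    if (t_max >= g_zero) {
      t_max_new <- max(c(0, test$time[test$time < g_zero]))
      warning(sprintf(
        "censoring survival reaches 0 at t = %g; truncating t_max from %g to %g",
        g_zero, t_max, t_max_new
      ))
      t_max <- t_max_new
    }
  }
  if (t_max <= 0) stop("no usable time range for the integrated Brier score")
  ev_times <- sort(unique(test$time[test$status == 1 & test$time <= t_max]))
  grid <- unique(c(0, ev_times[ev_times < t_max], t_max))
  surv_pred <- predict_survival(train, beta, test$covariates, grid)
  ibs_from_predictions(test$time, test$status, surv_pred, grid, censor_km = G)
}

#' Variable-selection counts against a known truth
#'
#' `var_count` is the number of nonzero estimated coefficients,
#' `corr_zeros` the number of true zeros estimated as zero, and
#' `incorr_zeros` the number of true nonzeros estimated as zero; the three
#' always sum to `p`.  Zero means bit-exact 0 (the shooting solvers
#' threshold to exact zeros), so no epsilon is applied.
#'
#' @param beta_hat Estimated coefficients.
#' @param beta_true True coefficients.
#' @return A list of class `selection_metrics` with `var_count`,
#'   `corr_zeros`, `incorr_zeros`.
#' @export
selection_metrics <- function(beta_hat, beta_true) {
  if (length(beta_hat) != length(beta_true)) stop("coefficient vectors differ in length")
  structure(
    list(
      var_count = sum(beta_hat != 0),
      corr_zeros = sum(beta_true == 0 & beta_hat == 0),
      incorr_zeros = sum(beta_true != 0 & beta_hat == 0)
    ),
    class = "selection_metrics"
  )
}
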