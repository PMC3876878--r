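# Risk scores, group split, Kaplan-Meier, log-rank, Breslow baseline,
# integrated Brier score and selection counts.

test_that("risk scores are the linear predictor", {
  X <- matrix(c(3, -1, 2, 0.5), 2, 2)
  expect_equal(risk_score(c(2, 0), X), c(6, -2))
  expect_equal(risk_score(c(0, 0), X), c(0, 0))
  # zero-coefficient covariates do not move the score
  expect_equal(risk_score(c(2, 0), X), risk_score(2, X[, 1, drop = FALSE]))
})

test_that("group split sends exact-cutoff scores to the low-risk group", {
  expect_identical(split_groups(c(-1, 0, 1)), c(0L, 0L, 1L))
  expect_identical(split_groups(c(2, 0.1)), c(1L, 1L))
  expect_identical(split_groups(numeric(0)), integer(0))
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- km_estimator(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$grid_times, 1:4)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))

  km <- km_estimator(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$grid_times, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))

  km <- km_estimator(c(1, 2, 3), c(0, 0, 0))
  expect_length(km$grid_times, 0)
  expect_equal(km_survival(km, c(0.5, 10)), c(1, 1))
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  t <- withr::with_seed(41, rexp(40))
  km <- km_estimator(t, rep(1, 40))
  for (x in c(0.1, 0.5, 1, 2)) {
    expect_equal(km_survival(km, x), mean(t > x))
  }
  # left limits: S(t-) at an event time is the value just before it
  expect_equal(km_survival(km, min(t), left = TRUE), 1)
})

test_that("log-rank statistic matches manual O-E/V arithmetic", {
  # groups A: 1(event) 3(event) 5(censored); B: 2, 4, 6 (all events)
  time <- c(1, 3, 5, 2, 4, 6)
  status <- c(1, 1, 0, 1, 1, 1)
  grp <- c(0, 0, 0, 1, 1, 1)
  E <- 1 / 2 + 2 / 5 + 1 / 2 + 1 / 3          # expected events in A
  V <- 1 / 4 + 6 / 25 + 1 / 4 + 2 / 9          # hypergeometric variance
  manual <- (2 - E)^2 / V
  lr <- logrank_test(time, status, grp)
  expect_equal(lr$statistic, manual, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(manual, 1, lower.tail = FALSE))

  # label swap leaves the statistic unchanged
  lr2 <- logrank_test(time, status, 1 - grp)
  expect_equal(lr$statistic, lr2$statistic, tolerance = 1e-12)
})

test_that("log-rank on duplicated groups is exactly null", {
  t <- c(1, 2, 3, 4); s <- c(1, 1, 0, 1)
  lr <- logrank_test(c(t, t), c(s, s), rep(c(0, 1), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank statistic has the chi-square df-1 permutation mean", {
  d <- toy_dataset(40, 2, seed = 43)
  stats <- withr::with_seed(44, vapply(1:200, function(i) {
    g <- sample(rep(0:1, each = 20))
    logrank_test(d$time, d$status, g)$statistic
  }, numeric(1)))
  expect_equal(mean(stats), 1, tolerance = 0.25)
})

test_that("Breslow baseline reduces to Nelson-Aalen at beta 0 and matches hand arithmetic", {
  d <- toy_dataset(30, 2, seed = 45)
  base <- baseline_survival(d, c(0, 0))
  # Nelson-Aalen: cumulative d_i / n_i at event times
  rs <- risk_sets(d$time, d$status)
  ev_times <- d$time[d$status == 1]
  ut <- sort(unique(ev_times))
  na <- cumsum(vapply(ut, function(t) {
    sum(ev_times == t) / sum(d$time >= t)
  }, numeric(1)))
  expect_equal(base$times, ut)
  expect_equal(base$cumhaz, na, tolerance = 1e-10)
  expect_true(all(diff(base$survival) <= 0))

  # n = 3 hand example with a covariate
  d3 <- survival_dataset(c(1, 2, 3), c(1, 0, 1), matrix(c(1, 0, -1), 3, 1))
  b <- 0.5
  w <- exp(c(1, 0, -1) * b)
  base3 <- baseline_survival(d3, b)
  expect_equal(base3$cumhaz, c(1 / sum(w), 1 / sum(w) + 1 / w[3]))
})

test_that("predicted survival obeys S(t|x) = S0(t)^exp(eta)", {
  d <- toy_dataset(30, 2, seed = 47)
  beta <- c(0.4, -0.3)
  base <- baseline_survival(d, beta)
  times <- c(0, base$times[1], max(base$times))
  P <- predict_survival(d, beta, d$covariates[1:3, , drop = FALSE], times)
  eta <- risk_score(beta, d$covariates[1:3, , drop = FALSE])
  H0 <- c(0, base$cumhaz[1], base$cumhaz[length(base$cumhaz)])
  expect_equal(P, exp(-outer(exp(eta), H0)), tolerance = 1e-12)
  expect_true(all(P >= 0 & P <= 1))
})

test_that("IBS is 0 for oracle predictions and 0.25 for the constant half", {
  t <- withr::with_seed(49, round(rexp(30) + 0.1, 3))
  s <- rep(1, 30)
  t_max <- unname(quantile(t, 0.95))
  grid <- c(0, sort(unique(t[t < t_max])), t_max)
  oracle <- outer(t, grid, FUN = ">")   # S(t|x_i) = 1{t_i > t}
  expect_equal(ibs_from_predictions(t, s, oracle * 1, grid), 0)
  half <- matrix(0.5, 30, length(grid))
  expect_equal(ibs_from_predictions(t, s, half, grid), 0.25)
})

test_that("IBS matches a brute-force double-loop on a censored toy", {
  train <- survival_dataset(
    time = c(1, 2, 3, 4, 5, 6, 7, 8),
    status = c(1, 0, 1, 1, 0, 1, 1, 0),
    covariates = matrix(c(0.5, -1, 0.2, 1.4, -0.7, 0.1, 0.9, -0.3), 8, 1)
  )
  test <- survival_dataset(
    time = c(1.5, 2.5, 3.5, 5.5, 7.5),
    status = c(1, 0, 1, 1, 0),
    covariates = matrix(c(0.3, -0.8, 1.1, -0.2, 0.6), 5, 1)
  )
  beta <- 0.6
  t_max <- 5.5
  got <- integrated_brier_score(train, test, beta, t_max = t_max)

  # brute force: explicit weights and trapezoid over the same grid
  G <- km_estimator(train$time, 1 - train$status)
  ev <- sort(unique(test$time[test$status == 1 & test$time <= t_max]))
  grid <- unique(c(0, ev[ev < t_max], t_max))
  S <- predict_survival(train, beta, test$covariates, grid)
  bs <- numeric(length(grid))
  for (k in seq_along(grid)) {
    tt <- grid[k]
    acc <- 0
    for (i in 1:5) {
      if (test$time[i] <= tt && test$status[i] == 1) {
        acc <- acc + (0 - S[i, k])^2 / km_survival(G, test$time[i], left = TRUE)
      } else if (test$time[i] > tt) {
        acc <- acc + (1 - S[i, k])^2 / km_survival(G, tt)
      }
    }
    bs[k] <- acc / 5
  }
  manual <- sum(diff(grid) * (head(bs, -1) + tail(bs, -1)) / 2) / t_max
  expect_equal(got, manual, tolerance = 1e-10)
})

test_that("IBS ignores pure-noise covariates with zero coefficients", {
  train <- toy_dataset(60, 2, seed = 51)
  test <- toy_dataset(40, 2, seed = 52)
  beta <- c(0.5, -0.4)
  i1 <- integrated_brier_score(train, test, beta)
  noise_tr <- cbind(train$covariates, matrix(rnorm(60 * 3), 60, 3))
  noise_te <- cbind(test$covariates, matrix(rnorm(40 * 3), 40, 3))
  train2 <- survival_dataset(train$time, train$status, noise_tr)
  test2 <- survival_dataset(test$time, test$status, noise_te)
  i2 <- integrated_brier_score(train2, test2, c(beta, 0, 0, 0))
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("selection metrics count Var / Corr / Incorr with bit-exact zeros", {
  bt <- true_beta(1000)
  sm <- selection_metrics(bt, bt)
  expect_equal(sm$var_count, 6)
  expect_equal(sm$corr_zeros, 994)
  expect_equal(sm$incorr_zeros, 0)

  sm0 <- selection_metrics(rep(0, 1000), bt)
  expect_equal(sm0$var_count, 0)
  expect_equal(sm0$corr_zeros, 994)
  expect_equal(sm0$incorr_zeros, 6)

  # identity var + corr + incorr = p on random sparsity patterns
  for (seed in 1:5) {
    bh <- withr::with_seed(seed, rnorm(50) * rbinom(50, 1, 0.3))
    bt2 <- withr::with_seed(seed + 100, rnorm(50) * rbinom(50, 1, 0.3))
    sm <- selection_metrics(bh, bt2)
    expect_equal(sm$var_count + sm$corr_zeros + sm$incorr_zeros, 50)
    expect_lte(sm$incorr_zeros, sum(bt2 != 0))
  }
  # a tiny float is NOT a zero
  expect_equal(selection_metrics(c(1e-300, 0), c(1, 1))$incorr_zeros, 1)
})
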