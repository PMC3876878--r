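# Shooting updates and the penalized fitting loops.

test_that("coordinate updates equal the brute-force 1-D minimizer", {
  set.seed(101)
  for (i in 1:200) {
    S0 <- runif(1, -10, 10)
    lam <- runif(1, 0, 5)
    w <- runif(1, 0.5, 2)
    hjj <- runif(1, 0.5, 2)
    expect_lt(abs(l1_shoot_update(S0, w, hjj, lam) -
                  grid_minimize(S0, lam * w, hjj)), 2e-4)
    expect_lt(abs(l12_shoot_update(S0, w, hjj, lam) -
                  grid_minimize(S0, lam * w / 2, hjj)), 2e-4)
  }
})

test_that("update formulas match their printed branches", {
  # third branch: exact zero when the threshold binds
  expect_identical(l12_shoot_update(1.9, 1, 1, 4), 0)   # |S0| <= lam*w/2
  expect_identical(l1_shoot_update(3.9, 1, 1, 4), 0)    # |S0| <= lam*w
  # worked branch values
  expect_equal(l12_shoot_update(10, 1, 1, 4), (4 - 20) / 4)  # -4
  expect_equal(l1_shoot_update(10, 1, 1, 4), (4 - 10) / 2)   # -3
  # lambda = 0 reduces to the quadratic vertex
  expect_equal(l1_shoot_update(3, 1, 2, 0), -3 / 4)
  # odd symmetry
  for (S0 in c(0.3, 2, 7)) {
    expect_equal(l12_shoot_update(-S0, 1.3, 0.8, 2), -l12_shoot_update(S0, 1.3, 0.8, 2))
    expect_equal(l1_shoot_update(-S0, 1.3, 0.8, 2), -l1_shoot_update(S0, 1.3, 0.8, 2))
  }
  expect_error(l1_shoot_update(1, 1, 0, 1), "degenerate")
  expect_error(l12_shoot_update(1, 1, -1, 1), "degenerate")
})

test_that("a coordinate zeroed by the L1 rule at lam*w/2 is zeroed by the L1/2 rule at lam*w", {
  set.seed(7)
  for (i in 1:100) {
    S0 <- runif(1, -5, 5); lam <- runif(1, 0.1, 4); w <- runif(1, 0.5, 2)
    if (abs(S0) <= lam * w / 2) {
      expect_identical(l1_shoot_update(S0, w, 1, lam / 2), 0)
      expect_identical(l12_shoot_update(S0, w, 1, lam), 0)
    }
  }
})

test_that("partial residual gradient matches the hand example", {
  # H = [[1, .5], [.5, 1]], b = [1, 0], beta = [0, 1], j = 1:
  # S0 = 2 * (0.5 * 1 - 1) = -1.  Encode H through its factor form
  # (X = chol(H), d = 1, no event-mean rows).
  H <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  surr <- structure(
    list(b = c(1, 0), diag = diag(H), H = H, X = chol(H), d = c(1, 1),
         M = matrix(0, 0, 2), p = 2L, n = 2L),
    class = "cox_surrogate"
  )
  expect_equal(partial_residual_gradient(surr, c(0, 1), 1), -1)
  # orthogonal null: H = I, b = 0 gives S0 = 0 in every coordinate
  surr0 <- structure(
    list(b = c(0, 0), diag = c(1, 1), H = diag(2), X = diag(2), d = c(1, 1),
         M = matrix(0, 0, 2), p = 2L, n = 2L),
    class = "cox_surrogate"
  )
  expect_equal(partial_residual_gradient(surr0, c(2, -3), 1), 0)
  expect_equal(partial_residual_gradient(surr0, c(2, -3), 2), 0)
})

test_that("partial residual gradient matches formula and finite differences", {
  d <- toy_dataset(40, 5, seed = 3, beta = c(0.5, -0.5, 0.3, 0, 0))
  surr <- linearize(d, rep(0.2, 5), with_const = TRUE)
  beta <- withr::with_seed(5, rnorm(5, sd = 0.4))
  for (j in 1:5) {
    S0 <- partial_residual_gradient(surr, beta, j)
    # formula from the dense H
    expect_equal(S0, 2 * (sum(surr$H[j, -j] * beta[-j]) - surr$b[j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # numerical derivative of the RSS in coordinate j at beta_j = 0
    h <- 1e-6
    bj <- replace(beta, j, h); bj2 <- replace(beta, j, -h)
    expect_equal(S0, (surrogate_rss(surr, bj) - surrogate_rss(surr, bj2)) / (2 * h),
                 tolerance = 1e-6)
  }
})

test_that("reweighted L1 pass solves the surrogate at lambda 0 and thresholds at large lambda", {
  d <- toy_dataset(40, 3, seed = 13)
  surr <- linearize(d, c(0.1, 0.1, 0.1))
  cfg <- solver_config(lam = 0)
  out <- reweighted_l1_pass(surr, rep(0, 3), cfg)
  expect_equal(out$beta, drop(solve(surr$H, surr$b)), tolerance = 1e-6,
               ignore_attr = TRUE)

  # all thresholds bind from the zero start
  surr0 <- linearize(d, rep(0, 3))
  lam_big <- 2 * max(abs(2 * surr0$b)) + 1
  cfg <- solver_config(lam = lam_big)
  out <- reweighted_l1_pass(surr0, rep(0, 3), cfg, fixed_weights = rep(1, 3))
  expect_identical(out$beta, rep(0, 3))
})

test_that("a fixed-weight sweep never increases the penalized surrogate objective", {
  d <- toy_dataset(40, 4, seed = 17, beta = c(0.5, -0.5, 0.3, 0))
  surr <- linearize(d, rep(0.5, 4), with_const = TRUE)
  lam <- 1.5
  w <- c(1, 2, 0.5, 1)
  objective <- function(b) surrogate_rss(surr, b) + lam * sum(w * abs(b))
  beta <- rep(0.5, 4)
  cfg <- solver_config(lam = lam, max_inner = 1)
  for (s in 1:8) {
    new_beta <- reweighted_l1_pass(surr, beta, cfg, fixed_weights = w)$beta
    expect_lte(objective(new_beta), objective(beta) + 1e-10)
    beta <- new_beta
  }
})

test_that("the L1/2 pass equals one reweighted-L1 sweep at half the penalty", {
  d <- toy_dataset(40, 4, seed = 19, beta = c(0.5, -0.5, 0.3, 0))
  beta_t <- c(0.4, -0.2, 0.05, 0.3)
  cfg <- solver_config(lam = 2)
  surr <- linearize(d, beta_t)
  a <- l12_pass(surr, beta_t, cfg)
  w <- (abs(beta_t) + cfg$epsilon)^(-1 / 2)
  cfg_half <- solver_config(lam = 1, max_inner = 1)
  b <- reweighted_l1_pass(surr, beta_t, cfg_half, fixed_weights = w)$beta
  expect_identical(a, b)
})

test_that("all three fits reduce to the Cox MLE at lambda 0", {
  d <- toy_dataset(50, 3, seed = 21)
  ref <- coxph_oracle(d)
  for (fit in list(lasso_fit(d, 0), adaptive_lasso_fit(d, 0), adaptive_l12_fit(d, 0))) {
    expect_lt(max(abs(fit$beta - ref)), 1e-4)
    expect_true(fit$converged)
  }
})

test_that("the null model is a fixed point at very large lambda", {
  d <- toy_dataset(60, 5, seed = 23, beta = c(0.8, -0.6, 0.4, 0, 0))
  lam <- 10 * lambda_grid(d, n_lambda = 2, ratio = 0.5)[1]
  for (fit in list(lasso_fit(d, lam), adaptive_lasso_fit(d, lam), adaptive_l12_fit(d, lam))) {
    expect_identical(unname(fit$beta), rep(0, 5))
  }
})

test_that("zeroed coefficients are bit-exact zeros and fits are deterministic", {
  d <- toy_dataset(80, 10, seed = 25, beta = c(1, -1, rep(0, 8)))
  lam <- lambda_grid(d, n_lambda = 5, ratio = 0.1)[3]
  f1 <- adaptive_l12_fit(d, lam)
  f2 <- adaptive_l12_fit(d, lam)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$objective_trace, f2$objective_trace)
  zeros <- f1$beta[f1$beta == 0]
  expect_true(length(zeros) > 0)
  expect_true(all(vapply(zeros, identical, logical(1), y = 0)))
})

test_that("unit weights make the adaptive lasso coincide with the lasso", {
  d <- toy_dataset(60, 4, seed = 27, beta = c(0.8, -0.6, 0, 0))
  lam <- 2
  cfg_unit <- solver_config(l1_exponent = 0)   # (|beta|+eps)^0 = 1
  fa <- adaptive_lasso_fit(d, lam, cfg_unit)
  fl <- lasso_fit(d, lam, cfg_unit)
  # both routes stop at fixed points of the same iteration at tol_outer
  expect_lt(max(abs(fa$beta - fl$beta)), 1e-4)
})

test_that("strong effects are recovered with matching signs at the CVPL-selected lambda", {
  beta_true <- c(0.9, -0.8, 0.7, rep(0, 17))
  cfg <- simulation_config(n = 200, p = 20, beta_true = beta_true, censor_rate = 0.25)
  d <- generate_dataset(cfg, seed = 1)
  sel <- select_lambda(d, "adaptive_l12", seed = 1, n_lambda = 25)
  fit <- adaptive_l12_fit(d, sel$lam_best)
  expect_true(all(fit$beta[1:3] != 0))
  expect_equal(sign(fit$beta[1:3]), sign(beta_true[1:3]), ignore_attr = TRUE)
})

test_that("the adaptive lasso is no denser than the lasso at its own scale", {
  cfg <- simulation_config(n = 200, p = 20,
                           beta_true = c(0.9, -0.8, 0.7, rep(0, 17)),
                           censor_rate = 0.25)
  d <- generate_dataset(cfg, seed = 2)
  lam <- lambda_grid(d, n_lambda = 10, ratio = 0.05)[6]
  expect_lte(sum(adaptive_lasso_fit(d, lam)$beta != 0),
             sum(lasso_fit(d, lam)$beta != 0))
})
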