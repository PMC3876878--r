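# Small seeded datasets used across the test files.  Everything is built
# in code at test time; nothing is read from disk.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_dataset <- function(n = 30, p = 3, seed = 1, beta = NULL,
                        censor_rate = 0.25) {
  if (is.null(beta)) beta <- c(0.8, -0.5, rep(0.3, p - 2))[1:p]
  cfg <- simulation_config(
    n = n, p = p, beta_true = beta, censor_rate = censor_rate,
    gompertz_a = 1, gompertz_gamma = 0.1
  )
  generate_dataset(cfg, seed = seed)
}

# reference unpenalized Cox fit (Breslow ties), used as the Newton oracle
coxph_oracle <- function(data) {
  fit <- survival::coxph(
    survival::Surv(data$time, data$status) ~ data$covariates,
    ties = "breslow", control = survival::coxph.control(eps = 1e-11)
  )
  unname(stats::coef(fit))
}

# brute-force 1-D minimizer of hjj*beta^2 + S0*beta + gamma*|beta| on a grid
grid_minimize <- function(S0, gamma, hjj, lo = -20, hi = 20, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  vals <- hjj * grid^2 + S0 * grid + gamma * abs(grid)
  grid[which.min(vals)]
}
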