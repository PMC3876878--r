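# coxL12

Variable selection and survival prediction for high-dimensional
right-censored data — typically gene-expression studies where thousands
of features are measured on a few hundred patients and only a handful
are expected to carry signal.

`coxL12` fits the Cox proportional-hazards model
`h(t | x) = h0(t) exp(beta' x)` under the nonconvex half-power penalty,

```
beta_hat = argmin  -l(beta) + lambda * sum_j |beta_j|^(1/2),
```

where `l` is the Breslow partial log-likelihood.  The optimizer is an
adaptive **L1/2 shooting** algorithm: each outer iteration linearizes
the partial likelihood (a Newton step expressed as a penalized
least-squares problem in normal-equation form), takes one half-power
shooting pass with weights `(|beta_j| + eps)^(-1/2)`, runs a
reweighted-L1 shooting pass to convergence with weights
`(|beta_j| + eps)^(-1)`, and keeps, coordinate by coordinate, the
candidate of smaller magnitude.  Coordinate updates are exact
soft-threshold minimizers, so discarded coefficients are bit-exact
zeros.  Lasso and adaptive-Lasso comparators share the same solver.
Tuning uses the Verweij–van Houwelingen cross-validated partial
likelihood (CVPL); evaluation covers Kaplan–Meier curves, the log-rank
test, Breslow baseline hazards, and the IPCW integrated Brier score
(IBS).  A Gompertz-baseline simulator with a sparse known truth and a
replication harness reproduce the method-comparison benchmark at
desk scale.

## Worked example

```r
library(coxL12)

# 200 subjects, 100 covariates, 6 true signals, 25% censoring
cfg   <- simulation_config(n = 200, p = 100, beta_true = true_beta(100),
                           censor_rate = 0.25)
train <- generate_dataset(cfg, seed = 5)
test  <- generate_dataset(cfg, seed = 6)

sel <- select_lambda(train, "adaptive_l12", seed = 1)
sel
#> cv_result (adaptive_l12): lambda_best = 6.24664 (CVPL = -789.5899) over 50 grid points

fit <- adaptive_l12_fit(train, sel$lam_best)
fit
#> cox_l12_fit (adaptive_l12): lambda = 6.24664, 14 nonzero of 100, 50 outer iterations (not converged)
which(fit$beta != 0)
#>  x1  x2  x3 x11 x14 x25 x49 x54 x67 x68 x77 x79 x95 x98
#>   1   2   3  11  14  25  49  54  67  68  77  79  95  98

sm <- selection_metrics(fit$beta, cfg$beta_true)
c(sm$var_count, sm$corr_zeros, sm$incorr_zeros)
#> [1] 14 85  1

scores <- risk_score(fit$beta, test$covariates)
groups <- split_groups(scores)            # 1 = high risk (score > 0)
logrank_test(test$time, test$status, groups)$p_value
#> [1] 1.046277e-14
integrated_brier_score(train, test, fit$beta)
#> [1] 0.1430894
```

Read: at the CVPL-chosen penalty the half-power fit keeps 14 of 100
covariates — five of the six true signals (positions 1, 2, 3, 11, 14)
plus nine false positives, missing only the weakest effect
(|beta| = 0.1) — and the resulting risk score splits the independent
test set into groups with clearly separated survival (log-rank
p ~ 1e-14).  The IBS of ~0.143 is the time-averaged squared error of the
predicted survival curves (0 is perfect, 0.25 is an uninformative
constant).  The "not converged" note is the nonconvex iteration hitting
its outer-iteration cap and returning its best iterate — common at
moderate penalties and documented in the methods vignette.

The same pipeline runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "coxL12.R", package = "coxL12"))')
Rscript $CLI simulate --n 200 --p 100 --censor-rate 0.25 --seed 5 --out train.tsv
Rscript $CLI cv       --data train.tsv --method al12 --seed 1 --out coef.tsv
Rscript $CLI evaluate --train train.tsv --test test.tsv --coef coef.tsv --out eval.json
```

Real data enter as a delimited survival table (`time`, `status`, one
column per feature; `read_survival_table()`) or as a features × samples
expression matrix joined to a clinical table
(`read_expression_matrix()`).

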