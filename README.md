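# einvpolicy

Effect-invariance testing and policy generalization across environments.

## The problem

Treatment policies (which push notification to send, whether to prescribe)
are learned from logged decisions collected in several *environments* —
users, sites, regimes — and must then act in a new environment where no
outcomes have been observed. Methods built on *full invariance* (the whole
conditional outcome distribution `Y | X_S` identical across environments)
often come up empty: any direct effect of the environment on the outcome
destroys full invariance for every subset. This package implements the
weaker, policy-sufficient notion of **effect-invariance**: a covariate
subset `S` is effect-invariant when the conditional average treatment
effect

```
tau_e^S(x) = E_e[Y | X_S = x, T = 1] - E_e[Y | X_S = x, T = 0]
```

is the same function of `x` in every environment, however much the outcome
level shifts. A policy that reads only an effect-invariant `S` ranks
treatments identically everywhere, so it transports to unseen environments,
and it provably dominates every covariate-free (constant) policy there.

The package provides, for tabular multi-environment bandit logs
(`y, t, env, prop` + covariates):

* **`wald_einv_test()`** — linear-CATE Wald test: treatment indicators
  centered by a fixed policy on `x_S`, propensity-ratio weighted least
  squares (a Neyman-orthogonal score robust to main-effect
  misspecification), sandwich covariance, chi-squared decision on the
  environment-by-treatment interaction block.
* **`dr_einv_test()`** — nonparametric test: sample splitting, per-
  environment outcome nuisances, doubly robust pseudo-outcomes whose
  conditional mean given `x_S` is the CATE, and a multi-environment
  generalised covariance measure for conditional-mean equality across
  environments.
* **`learn_einv_policy()`** — zero-shot policy learning: Lasso screening,
  subset enumeration and testing, pooled CATE fits on accepted subsets,
  argmax policies, and selection of the best subset on the test
  environment's covariates (outcome-free).
* **`few_shot_fit()`** — few-shot adaptation: constrained CATE estimation
  from a small labeled test sample, with the training-environment CATE on
  the invariant subset as a projection constraint under an additive
  separability assumption (closed-form linear solution).
* **`simulate_intro()`, `simulate_example1()`, `simulate_mrt_fixture()`,
  `simulate_separable()`** — seeded structural-causal-model generators
  with ground-truth CATE oracles, including a micro-randomized-trial-like
  multi-user fixture.
* **`fit_outcome_model()`, `residual_bootstrap_value()`,
  `leave_one_env_out()`** — semi-synthetic policy evaluation by residual
  bootstrap with common random numbers and a paired signed-rank
  comparison.

## Worked example

Two training environments from the three-covariate latent-confounder
model: `X1` and `X3` load on a latent effect modifier `U1` with loadings
that differ across environments, while `X2` is independent of `U1` — so
`{x2}` is the only informative effect-invariant subset.

```r
library(einvpolicy)

params <- list(list(gamma1 =  1.0, gamma2 = 1.0, gamma3 =  1.0, mu = 0),
               list(gamma1 = -1.5, gamma2 = 0.5, gamma3 = -1.5, mu = 1))
sim <- simulate_example1(params, n_per_env = 4000, seed = 1)
sim$data
#> <multienv_data> n = 8000, d = 3 covariates (x1, x2, x3), 2 environments, k = 2 treatments

for (S in list("x1", "x2", "x3")) print(wald_einv_test(sim$data, S))
#> <wald e-invariance test> S = {x1}: statistic = 40.768, df = 4, p = 3.002e-08 -> reject at alpha = 0.05
#> <wald e-invariance test> S = {x2}: statistic = 1.540, df = 4, p = 0.8195 -> accept at alpha = 0.05
#> <wald e-invariance test> S = {x3}: statistic = 40.497, df = 4, p = 3.416e-08 -> reject at alpha = 0.05

dr_einv_test(sim$data, "x2", config = list(seed = 1))
#> <dr e-invariance test> S = {x2}: statistic = 0.237, df = 1, p = 0.6261 -> accept at alpha = 0.05
```

Subsets involving `x1` or `x3` are rejected (their CATEs change with the
environment-specific loadings); `{x2}` is accepted by both tests. Zero-shot
learning picks the accepted subset whose argmax policy collects the largest
estimated effect on covariates from a *new* environment:

```r
x_test <- simulate_example1(draw_example1_params(1, seed = 99), 500,
                            seed = 100)$data$x
zs <- learn_einv_policy(sim$data, x_test, method = "wald",
                        config = list(seed = 2, screen = FALSE))
zs
#> <zero_shot_result> S* = {x2}; criterion:
#>     {}     x2
#> 1.0763 1.1549

predict(zs$policy, rbind(c(0, -3, 0), c(0, 0, 0), c(0, 3, 0)) |>
          `colnames<-`(c("x1", "x2", "x3")))
#>      [,1] [,2]
#> [1,]    1    0
#> [2,]    0    1
#> [3,]    0    1
```

The criterion row reads: the empty subset's best policy (always treat,
since the pooled average effect is positive) collects an estimated 1.076
per decision; the `{x2}`-argmax policy collects 1.155. The fitted CATE on
`{x2}` is approximately `1 + 0.5 x2` (estimates `-0.31, 1.09, 2.48` at
`x2 = -3, 0, 3`), so the learned policy treats exactly when the estimated
effect is positive — it withholds treatment at `x2 = -3` and treats at
`x2 = 0` and `3`, matching the oracle rule `treat iff x2 > -2`.

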