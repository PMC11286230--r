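# Residual-bootstrap policy evaluation.

test_that("noiseless model data is interpolated exactly", {
  set.seed(1)
  n <- 60
  x <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
  t <- rbinom(n, 1, 0.5)
  alpha <- c(1, 0.5, -0.2); beta <- c(0.3, 1, 0)
  y <- drop(cbind(1, x) %*% alpha) + drop(cbind(1, x) %*% beta) * t
  d <- multienv_data(y, x, t, rep("e", n), rep(0.5, n))
  fit <- fit_outcome_model(d)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(unname(fit$alpha_coef), alpha)
  expect_equal(unname(fit$beta_coef), beta)
  # duplicated dataset gives the identical fit
  d2 <- multienv_data(rep(y, 2), rbind(x, x), rep(t, 2), rep("e", 2 * n),
                      rep(0.5, 2 * n))
  fit2 <- fit_outcome_model(d2)
  expect_equal(fit2$alpha_coef, fit$alpha_coef)
  expect_equal(fit2$beta_coef, fit$beta_coef)
})

test_that("pure-noise outcomes give near-zero treatment coefficients", {
  set.seed(2)
  n <- 20000
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "a"))
  t <- rbinom(n, 1, 0.5)
  y <- rnorm(n)
  d <- multienv_data(y, x, t, rep("e", n), rep(0.5, n))
  fit <- fit_outcome_model(d)
  # crude SE bound: sd(y) / sqrt(n / 4 arms)
  expect_lt(max(abs(fit$beta_coef)), 3 * 4 / sqrt(n))
})

test_that("bootstrap value matches hand-computed expectations", {
  # two-row fixture, zero residuals, treatment effects (1, 3)
  x <- matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "a"))
  y <- c(10 + 1, 20 + 3)          # baseline 10/20 plus effect under t = 1
  d <- multienv_data(y, x, c(1L, 1L), c("e", "e"), rep(0.5, 2))
  # cannot fit 4 coefficients on 2 rows; build the fit object directly
  fit <- structure(list(alpha_coef = c(10, 10), beta_coef = c(1, 2),
                        residuals = c(0, 0), x = x,
                        f_vars = "a", g_vars = "a"),
                   class = "outcome_model_fit")
  v <- residual_bootstrap_value(fit, constant_policy(1), n_boot = 4000,
                                seed = 3)
  # E[baseline] = 15, E[effect] = (1 + 3) / 2 = 2 -> 17
  expect_lt(abs(v - 17), 3 * sd(c(11, 23)) / sqrt(4000))
  # beta = 0: value ignores the policy entirely
  fit0 <- fit; fit0$beta_coef <- c(0, 0)
  v1 <- residual_bootstrap_value(fit0, constant_policy(1), 500, seed = 4)
  v0 <- residual_bootstrap_value(fit0, constant_policy(0), 500, seed = 4)
  expect_equal(v1, v0)
  # determinism
  expect_equal(residual_bootstrap_value(fit, bernoulli_policy(0.4), 200, 5),
               residual_bootstrap_value(fit, bernoulli_policy(0.4), 200, 5))
  expect_error(residual_bootstrap_value(fit, constant_policy(1), 0), "n_boot")
})

test_that("relative value uses common random numbers", {
  sim <- simulate_mrt_fixture(3, 80, seed = 6)
  d1 <- subset_records(sim$data, sim$data$env == levels(sim$data$env)[1])
  fit <- fit_outcome_model(d1, f_vars = c("db", "ae", "lc", "vi"))
  # self-comparison cancels exactly
  expect_identical(relative_value(fit, constant_policy(0),
                                  baseline = constant_policy(0), seed = 7), 0)
  # repeated calls agree bit for bit
  p <- bernoulli_policy(0.3)
  expect_identical(relative_value(fit, p, n_boot = 300, seed = 8),
                   relative_value(fit, p, n_boot = 300, seed = 8))
  # relative value of always-treat equals the resampled mean effect
  draws_val <- relative_value(fit, constant_policy(1), n_boot = 2000,
                              seed = 9)
  set.seed(9)
  idx <- sample.int(length(fit$residuals), 2000, replace = TRUE)
  eff <- drop(cbind(1, fit$x[idx, fit$f_vars]) %*% fit$beta_coef)
  expect_equal(draws_val, mean(eff))
})

test_that("bootstrap value converges to the plug-in value", {
  sim <- simulate_mrt_fixture(2, 150, seed = 10)
  d1 <- subset_records(sim$data, sim$data$env == levels(sim$data$env)[1])
  fit <- fit_outcome_model(d1, f_vars = c("db", "ae", "lc", "vi"))
  pol <- bernoulli_policy(0.6)
  plug_in <- mean(drop(cbind(1, fit$x[, fit$g_vars]) %*% fit$alpha_coef) +
                    0.6 * drop(cbind(1, fit$x[, fit$f_vars]) %*%
                                 fit$beta_coef) + fit$residuals)
  v <- residual_bootstrap_value(fit, pol, n_boot = 5000, seed = 11)
  spread <- sd(d1$y) / sqrt(5000)
  expect_lt(abs(v - plug_in), 4 * spread)
})

test_that("uniform policy value sits between the constant-policy values", {
  # monotone-effect fixture: all treatment effects positive
  sim <- simulate_mrt_fixture(2, 200, coef_config = list(
    beta_mean = c(intercept = 2, db = 0.2, ae = 0.2, lc = 0.2, vi = 0.2),
    beta_sd = 0), seed = 12)
  d1 <- subset_records(sim$data, sim$data$env == levels(sim$data$env)[1])
  fit <- fit_outcome_model(d1, f_vars = c("db", "ae", "lc", "vi"))
  v0 <- relative_value(fit, constant_policy(0), n_boot = 2000, seed = 13)
  v1 <- relative_value(fit, constant_policy(1), n_boot = 2000, seed = 13)
  vu <- relative_value(fit, uniform_policy(), n_boot = 2000, seed = 13)
  expect_true(v0 <= vu && vu <= v1)
})

test_that("leave-one-environment-out prefers the invariant policy under drift", {
  # one strongly environment-varying coefficient (ae); subsets containing ae
  # destabilize the CATE across users
  # effects straddle zero so argmax policies genuinely disagree, and the
  # destabilized feature (ae) has no exploitable cohort-average benefit
  sim <- simulate_mrt_fixture(6, 300, coef_config = list(
    beta_mean = c(intercept = 0, db = 0.3, ae = 0, lc = 0.3, vi = 0.5),
    beta_sd = 2.5,
    invariant_features = c("intercept", "db", "lc", "vi")), seed = 14)
  res <- leave_one_env_out(sim$data, f_vars = c("db", "ae", "lc", "vi"),
                           n_boot = 800, seed = 14)
  expect_s3_class(res, "loeo_result")
  expect_equal(nrow(res$table), 6L)
  expect_true(all(c("einv", "full", "random") %in% names(res$table)))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_gte(res$wins, 4)   # majority of held-out users
  expect_error(leave_one_env_out(subset_records(sim$data,
                                                sim$data$env %in% levels(sim$data$env)[1:2])),
               "3 environments")
})
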