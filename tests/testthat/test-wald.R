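# Wald effect-invariance test: centering, weighting, estimating equations.

test_that("treatment centering subtracts the fixed policy's probability", {
  xS <- matrix(c(0.3, -1), ncol = 1, dimnames = list(NULL, "x2"))
  expect_equal(center_treatment(c(1L, 0L), xS, bernoulli_policy(0.5)),
               c(0.5, -0.5))
  # centering policy must live in Pi_S
  bad <- new_policy(function(x) cbind(0.5, 0.5), support_subset = "x9")
  expect_error(center_treatment(c(1L, 0L), xS, bad), "outside S")
  # centering identity: E[C | x] = 0 under T ~ pi_tilde
  q <- 0.3
  expect_equal(q * (1 - q) + (1 - q) * (0 - q), 0)
})

test_that("weights are the likelihood ratio at the realized action", {
  d <- small_example1(200, seed = 2)
  # pi_tilde equal to the logging policy restricted to its support:
  # here the logging policy uses all covariates, so use a dataset logged
  # by a Bernoulli policy and center with the same policy -> weights 1
  sim <- simulate_example1(fixed_params, 200, policy = bernoulli_policy(0.4),
                           seed = 2)
  w <- compute_weights(sim$data, character(0), bernoulli_policy(0.4))
  expect_equal(w, rep(1, sim$data$n))
  # hand ratio: pi_tilde(1|.) = 0.5, prop = 0.25, t = 1 -> 2
  d2 <- multienv_data(c(1, 2), matrix(0, 2, 1, dimnames = list(NULL, "x")),
                      c(1L, 0L), c("a", "b"), c(0.25, 0.5))
  expect_equal(compute_weights(d2, "x", bernoulli_policy(0.5)), c(2, 1))
  # always finite and positive under positivity
  w3 <- compute_weights(d, "x2", bernoulli_policy(0.5))
  expect_true(all(is.finite(w3) & w3 > 0))
})

test_that("fit_gmm equals an independent weighted least-squares solve", {
  # oracle: direct normal-equations solve on the same design and weights
  for (rep in 1:10) {
    set.seed(100 + rep)
    n <- 120
    x <- matrix(rnorm(3 * n), ncol = 3,
                dimnames = list(NULL, c("x1", "x2", "x3")))
    t <- rbinom(n, 1, 0.5)
    env <- sample(c("a", "b"), n, replace = TRUE)
    prop <- runif(n, 0.2, 0.8)
    prop <- ifelse(t == 1, prop, 1 - prop)
    y <- rnorm(n)
    d <- multienv_data(y, x, t, env, prop)
    fit <- fit_gmm(d, "x2")
    # independent solve: rebuild design naively and use solve()
    C <- (t == 1) - 0.5
    xt <- cbind(1, x); xtS <- cbind(1, x[, "x2"])
    ind <- as.numeric(factor(env)) == 2
    D <- cbind(xt, xt * ind, xtS * C, xtS * (C * ind))
    W <- 0.5 / d$prop
    theta <- solve(t(D) %*% (D * W), t(D) %*% (W * y))
    expect_lt(max(abs(unname(fit$coef) - drop(theta))), 1e-8)
  }
})

test_that("duplicated environments force a zero interaction and p = 1", {
  d <- duplicated_env_data(300)
  fit <- fit_gmm(d, "x2")
  expect_lt(max(abs(fit$B_hat)), 1e-8)
  res <- wald_einv_test(d, "x2")
  expect_lt(res$statistic, 1e-10)
  expect_equal(res$p_value, 1)
  expect_false(res$reject)
})

test_that("fit_gmm recovers known interaction coefficients", {
  # data generated directly from the working model with B != 0
  set.seed(31)
  n <- 1e5
  x <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  env <- rep(c("a", "b"), each = n / 2)
  t <- rbinom(n, 1, 0.5)
  C_true <- (t == 1) - 0.5
  B_true <- c(0.4, -0.3)   # environment-b deviation on (1, x2)
  y <- 1 + x[, 1] + 2 * x[, 2] + (env == "b") * (0.5 - x[, 1]) +
    C_true * (1 + 0.5 * x[, 2]) +
    C_true * (env == "b") * (B_true[1] + B_true[2] * x[, 2]) + rnorm(n)
  d <- multienv_data(y, x, t, env, ifelse(t == 1, 0.5, 0.5))
  fit <- fit_gmm(d, "x2")
  se <- sqrt(diag(fit$V_hat) / n)
  expect_true(all(abs(fit$b_vec - B_true) < 3 * se))
})

test_that("rank-deficient designs raise a degenerate-design error", {
  set.seed(32)
  n <- 100
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x1"))
  x <- cbind(x, x1copy = x[, 1])   # perfectly collinear column
  d <- multienv_data(rnorm(n), x, rbinom(n, 1, 0.5),
                     rep(c("a", "b"), n / 2), rep(0.5, n))
  expect_error(fit_gmm(d, "x1"), "degenerate design")
  # fewer than two environments
  d1 <- multienv_data(rnorm(n), x[, 1, drop = FALSE], rbinom(n, 1, 0.5),
                      rep("a", n), rep(0.5, n))
  expect_error(fit_gmm(d1, "x1"), "2 environments")
})

test_that("p-value is invariant to environment relabeling", {
  d <- small_example1(400, seed = 33)
  p1 <- wald_einv_test(d, "x2")$p_value
  relabeled <- multienv_data(d$y, d$x, d$t,
                             c(e1 = "zz", e2 = "aa")[as.character(d$env)],
                             d$prop)
  p2 <- wald_einv_test(relabeled, "x2")$p_value
  expect_lt(abs(p1 - p2), 1e-10)
})

test_that("statistic is invariant to affine rescaling of non-S covariates", {
  d <- small_example1(400, seed = 34)
  s1 <- wald_einv_test(d, "x2")$statistic
  x2 <- d$x
  x2[, "x1"] <- 3 * x2[, "x1"] - 5
  x2[, "x3"] <- -0.5 * x2[, "x3"] + 2
  d2 <- multienv_data(d$y, x2, d$t, as.character(d$env), d$prop)
  expect_equal(wald_einv_test(d2, "x2")$statistic, s1, tolerance = 1e-6)
})

test_that("the empty subset is testable with intercept-only blocks", {
  d <- small_example1(400, seed = 35)
  res <- wald_einv_test(d, character(0))
  expect_equal(res$df, 2L)                # block df: l * (1 + 0)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  res_rank <- wald_einv_test(d, character(0), df = "rank")
  expect_equal(res_rank$df, 1L)
  expect_equal(res$statistic, res_rank$statistic)
})

test_that("estimated-propensity mode warns about the covariance", {
  d <- small_example1(200, seed = 36)
  expect_warning(wald_einv_test(d, "x2", propensity_estimated = TRUE),
                 "covariance")
})

test_that("treatment-effect coefficients stay consistent under nonlinear main effects", {
  # Neyman orthogonality: pooled beta estimates the linear CATE on x2 even
  # though the main effect has an x2*x3 interaction the model cannot fit
  sim <- simulate_example1(fixed_params, 25000, variant = "nonlinear_main",
                           seed = 37)
  fit <- fit_gmm(sim$data, "x2")
  beta <- fit$beta_hat
  expect_lt(abs(beta[1] - 1.0), 0.12)   # intercept of 1 + 0.5 x2
  expect_lt(abs(beta[2] - 0.5), 0.12)
})
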