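# Core types, policies, pseudo-outcomes and pooled CATE estimation.

test_that("multienv_data validates its invariants", {
  x <- matrix(rnorm(10), ncol = 2, dimnames = list(NULL, c("a", "b")))
  d <- multienv_data(rnorm(5), x, c(0, 1, 0, 1, 1), c(1, 1, 2, 2, 2),
                     rep(0.5, 5))
  expect_s3_class(d, "multienv_data")
  expect_equal(d$n, 5L)
  expect_equal(nlevels(d$env), 2L)
  # unequal lengths
  expect_error(multienv_data(rnorm(4), x, rep(0L, 5), rep(1, 5), rep(.5, 5)),
               "equal length")
  # positivity: zero / tiny propensities rejected, not clipped
  expect_error(multienv_data(rnorm(5), x, rep(0L, 5), rep(1, 5),
                             c(0.5, 0.5, 0.5, 0.5, 1e-8)), "positivity")
  # missing values rejected, not imputed
  expect_error(multienv_data(c(NA, rnorm(4)), x, rep(0L, 5), rep(1, 5),
                             rep(.5, 5)), "missing")
  # invalid treatment level
  expect_error(multienv_data(rnorm(5), x, c(0, 1, 2, 0, 1), rep(1, 5),
                             rep(.5, 5)), "treatment")
})

test_that("treatment_space enforces k >= 2 and t0 in range", {
  expect_error(treatment_space(1), "k")
  expect_error(treatment_space(2, 2), "t0")
  expect_equal(treatment_space(3, 1)$t0, 1L)
})

test_that("constant and Bernoulli policies behave as point mass / coin flip", {
  x <- matrix(rnorm(6), ncol = 2)
  expect_equal(predict(constant_policy(0), x),
               cbind(rep(1, 3), rep(0, 3)))
  expect_equal(predict(bernoulli_policy(0.5), x),
               cbind(rep(0.5, 3), rep(0.5, 3)))
  # context-free: identical outputs at distinct covariate values
  p <- predict(bernoulli_policy(0.3), x)
  expect_equal(p[1, ], p[3, ])
  expect_equal(unname(p[1, ]), c(0.7, 0.3))
  expect_error(bernoulli_policy(1), "strictly inside")
  expect_error(bernoulli_policy(0), "strictly inside")
})

test_that("pseudo-outcome reduces to the model contrast when y is on-model", {
  # y equals mu(x, t) for the observed arm: correction terms vanish
  mu1 <- 2; mu0 <- 1
  expect_equal(pseudo_outcome(y = 2, t = 1L, mu1, mu0, p1 = 0.7), 1)
  expect_equal(pseudo_outcome(y = 1, t = 0L, mu1, mu0, p1 = 0.7), 1)
  # hand evaluation: mu1=2, mu0=1, p=0.5, t=1, y=3 -> 1 + (3-2)/0.5 = 3
  expect_equal(pseudo_outcome(3, 1L, 2, 1, 0.5), 3)
  expect_error(pseudo_outcome(1, 1L, 2, 1, 1), "positivity")
  expect_error(pseudo_outcome(1, 2L, 2, 1, 0.5), "binary")
})

test_that("pseudo-outcome is unbiased for the CATE under the intro model", {
  # Monte-Carlo check at a fixed covariate band: correct propensities,
  # deliberately crude (zero) outcome model
  n <- 1e5
  sim <- simulate_intro(1, n, seed = 42)
  d <- sim$data
  p1 <- ifelse(d$t == 1L, d$prop, 1 - d$prop)
  o <- pseudo_outcome(d$y, d$t, mu1 = rep(0, n), mu0 = rep(0, n), p1 = p1)
  band <- abs(d$x[, 1]) < 0.1
  est <- mean(o[band])
  se <- sd(o[band]) / sqrt(sum(band))
  expect_lt(abs(est - 1.0), 3 * se)   # true CATE at x ~ 0 is 1 + x ~ 1
})

test_that("pooled CATE recovers the intro model oracle 1 + x", {
  sim <- simulate_intro(c(1, -1), 25000, seed = 7)
  tau <- pooled_cate_fit(sim$data, "x", seed = 7)
  grid <- matrix(c(-2, -1, 0, 1, 2), ncol = 1, dimnames = list(NULL, "x"))
  expect_lt(max(abs(predict(tau, grid) - (1 + grid[, 1]))), 0.1)
  # baseline arm is exactly zero
  expect_equal(predict(tau, grid, t = 0L), rep(0, 5))
})

test_that("pooled CATE recovers the three-covariate model oracle on x2", {
  sim <- simulate_example1(fixed_params, 25000, seed = 8)
  tau <- pooled_cate_fit(sim$data, "x2", seed = 8)
  grid <- matrix(c(-2, 0, 2), ncol = 1, dimnames = list(NULL, "x2"))
  expect_lt(max(abs(predict(tau, grid) - (1 + 0.5 * grid[, 1]))), 0.1)
})

test_that("pooled CATE is near zero when treatment has no effect", {
  # null effect: y ignores t entirely
  set.seed(9)
  n <- 20000
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
  t <- rbinom(n, 1, 0.5)
  y <- x[, 1] + rnorm(n)
  d <- multienv_data(y, x, t, rep(c("a", "b"), n / 2), rep(0.5, n))
  tau <- pooled_cate_fit(d, "x", seed = 9)
  grid <- matrix(seq(-2, 2, by = 0.5), ncol = 1, dimnames = list(NULL, "x"))
  expect_lt(max(abs(predict(tau, grid))), 0.1)
  # single-arm data is a degenerate design
  d1 <- multienv_data(y, x, rep(1L, n), rep(c("a", "b"), n / 2), rep(0.5, n))
  expect_error(pooled_cate_fit(d1, "x"), "arm")
})

test_that("pooled CATE is invariant to record order and environment labels", {
  d <- small_example1(1000, seed = 10)
  grid <- matrix(c(-1, 0, 1), ncol = 1, dimnames = list(NULL, "x2"))
  tau <- pooled_cate_fit(d, "x2", seed = 1)
  set.seed(11)
  perm <- sample(d$n)
  d2 <- subset_records(d, perm)
  tau2 <- pooled_cate_fit(d2, "x2", seed = 1)
  expect_equal(predict(tau, grid), predict(tau2, grid), tolerance = 1e-8)
  d3 <- multienv_data(d$y, d$x, d$t,
                      c(e1 = "zz", e2 = "aa")[as.character(d$env)],
                      d$prop)
  tau3 <- pooled_cate_fit(d3, "x2", seed = 1)
  expect_equal(predict(tau, grid), predict(tau3, grid), tolerance = 1e-8)
})

test_that("double robustness: one correct nuisance suffices", {
  # intro model, fixed environment e = 1: true mu(x, t) = t(1+x) + x + 2 + E[u|x]
  n <- 6e4
  sim <- simulate_intro(1, n, seed = 21)
  d <- sim$data
  xv <- d$x[, 1]
  mu_true_1 <- (1 + xv) + xv + 2 + xv / 2   # E[U | X = x] = x/2 when e = 1
  mu_true_0 <- xv + 2 + xv / 2
  p_true <- ifelse(d$t == 1L, d$prop, 1 - d$prop)
  band <- abs(xv - 1) < 0.1                 # CATE there is ~ 2
  # (a) correct mu, badly wrong propensity model
  o_a <- pseudo_outcome(d$y, d$t, mu_true_1, mu_true_0,
                        p1 = rep(0.2, n))
  est_a <- mean(o_a[band]); se_a <- sd(o_a[band]) / sqrt(sum(band))
  expect_lt(abs(est_a - 2), 3 * se_a + 0.05)
  # (b) wrong mu (zero), correct propensities
  o_b <- pseudo_outcome(d$y, d$t, rep(0, n), rep(0, n), p_true)
  est_b <- mean(o_b[band]); se_b <- sd(o_b[band]) / sqrt(sum(band))
  expect_lt(abs(est_b - 2), 3 * se_b + 0.05)
})
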