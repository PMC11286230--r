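## Structural-causal-model simulators with ground-truth CATE oracles.
##
## Every generator returns a `sim_output`: the logged dataset, the latent
## draws, a CATE oracle on the designated effect-invariant subset and a
## full-information oracle tau(x, u) used for exact policy-value evaluation.

new_sim_output <- function(data, latent, truth, truth_full) {
  structure(list(data = data, latent = latent, truth = truth,
                 truth_full = truth_full), class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("<sim_output>\n"); print(x$data); invisible(x)
}

## internal: draw treatments from a policy and record realized propensities
draw_treatments <- function(policy, x) {
  p <- predict(policy, x)
  u <- stats::runif(nrow(x))
  t <- as.integer(u < p[, 2L])
  list(t = t, prop = ifelse(t == 1L, p[, 2L], p[, 1L]))
}

#' Logging policy of the single-covariate introductory model
#'
#' The built-in treatment mechanism `T = 1{1 + X + eps_T > 0}` with standard
#' normal `eps_T`, i.e. `P(T = 1 | X = x) = pnorm(1 + x)`.
#'
#' @return A [new_policy()] over a single covariate `x`.
#' @export
intro_default_policy <- function() {
  new_policy(function(x) {
    p1 <- stats::pnorm(1 + x[, 1L])
    cbind(1 - p1, p1)
  }, k = 2L, support_subset = "x", label = "1{1 + x + eps > 0}")
}

#' Simulate the single-covariate two-mechanism introductory model
#'
#' Per record in environment `e`: `U = eps_U`, `X = e * U + eps_X`,
#' `T ~ policy(X)` and `Y = T (1 + X) + X + 2 e + U + eps_Y`, all noises
#' standard normal. The CATE given `X` equals `1 + x` in every environment,
#' so `{x}` is effect-invariant, while no subset satisfies full invariance
#' (the environment shifts the outcome directly).
#'
#' @param environments Numeric vector of environment parameters `e`.
#' @param n_per_env Records per environment.
#' @param policy Logging policy over the single covariate; default the
#'   built-in threshold mechanism [intro_default_policy()].
#' @param seed Integer seed.
#' @return A `sim_output` with dataset covariate column `x`, latent column
#'   `u`, oracle `truth` (the CATE given `x`) and `truth_full(x, u)`.
#' @export
simulate_intro <- function(environments, n_per_env,
                           policy = intro_default_policy(), seed = 1L) {
  stopifnot(length(environments) >= 1L, n_per_env >= 0L)
  set.seed(seed)
  ys <- xs <- us <- props <- numeric(0)
  ts <- integer(0); envs <- character(0)
  for (e in environments) {
    u <- stats::rnorm(n_per_env)
    x <- e * u + stats::rnorm(n_per_env)
    xm <- matrix(x, ncol = 1L, dimnames = list(NULL, "x"))
    dr <- draw_treatments(policy, xm)
    y <- dr$t * (1 + x) + x + 2 * e + u + stats::rnorm(n_per_env)
    ys <- c(ys, y); xs <- c(xs, x); us <- c(us, u)
    ts <- c(ts, dr$t); props <- c(props, dr$prop)
    envs <- c(envs, rep(format(e), n_per_env))
  }
  xm <- matrix(xs, ncol = 1L, dimnames = list(NULL, "x"))
  truth <- cate_function("x", function(xS) 1 + xS[, 1L])
  truth_full <- function(x, u) 1 + x[, 1L]
  data <- if (length(ys) == 0L) {
    ## empty dataset: keep the container shape without validation short-cuts
    structure(list(y = numeric(0), x = xm, t = integer(0),
                   env = factor(character(0)), prop = numeric(0),
                   space = treatment_space(2L), n = 0L),
              class = "multienv_data")
  } else multienv_data(ys, xm, ts, envs, props)
  new_sim_output(data, matrix(us, ncol = 1L, dimnames = list(NULL, "u")),
                 truth, truth_full)
}

#' Logging policy used by the three-covariate simulation study
#'
#' `P(T = 1 | x) = 1 / (1 + exp(-0.5 + x1 - 0.5 x2 + 0.3 x3))`.
#'
#' @return A [new_policy()] over covariates `x1, x2, x3`.
#' @export
#' @examples
#' predict(default_training_policy(), matrix(0, 1, 3,
#'         dimnames = list(NULL, c("x1", "x2", "x3"))))[, 2]  # 0.6225
default_training_policy <- function() {
  new_policy(function(x) {
    p1 <- 1 / (1 + exp(-0.5 + x[, 1L] - 0.5 * x[, 2L] + 0.3 * x[, 3L]))
    cbind(1 - p1, p1)
  }, k = 2L, support_subset = c("x1", "x2", "x3"),
  label = "logistic(-0.5 + x1 - 0.5 x2 + 0.3 x3)")
}

#' Draw environment parameters for the three-covariate model
#'
#' Independent Uniform[-3, 3] draws of `(gamma1, gamma2, gamma3, mu)` per
#' environment, the study's default environment-parameter distribution.
#'
#' @param n_env Number of environments.
#' @param seed Integer seed.
#' @return A list of per-environment parameter lists.
#' @export
draw_example1_params <- function(n_env, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_env), function(i) {
    v <- stats::runif(4, -3, 3)
    list(gamma1 = v[1], gamma2 = v[2], gamma3 = v[3], mu = v[4])
  })
}

#' Simulate the three-covariate latent-confounder model
#'
#' Structural equations per environment (all noises standard normal):
#' `U1 = eps_U1`, `U2 = eps_U2`, `X1 = gamma1 U1 + eps_X1`,
#' `X2 = gamma2 U2 + eps_X2`, `X3 = gamma3 U1 + eps_X3`, `T ~ policy(X)`,
#' and, by variant,
#' \itemize{
#'   \item `linear`: `Y = T (1 + 0.5 X2 + 0.5 U1) + U1 + U2 + X2 + X3 + mu + eps_Y`
#'   \item `nonlinear_main`: `Y = T (1 + 0.5 X2 + 0.5 U1) + U1 + X2 + mu + U2 - 0.5 X2 X3 + X3 + eps_Y`
#'   \item `nonlinear_cate`: `Y = T (1 + 0.5 X2^2 + 0.5 X2^3 + 0.5 U1) + U1 + X2 + mu + U2 - 0.5 X2 X3 + X3 + eps_Y`
#' }
#' Since `U1` is independent of `X2`, the subset `{x2}` is effect-invariant
#' in every variant; subsets involving `x1` or `x3` are not whenever the
#' loadings `gamma1`, `gamma3` differ across environments.
#'
#' @param env_params List of per-environment lists with elements `gamma1`,
#'   `gamma2`, `gamma3`, `mu` (see [draw_example1_params()]).
#' @param n_per_env Records per environment.
#' @param policy Logging policy; default [default_training_policy()].
#' @param variant One of `"linear"`, `"nonlinear_main"`, `"nonlinear_cate"`.
#' @param seed Integer seed.
#' @return A `sim_output` with covariates `x1, x2, x3`, latents `u1, u2`,
#'   `truth` = CATE given `x2` and `truth_full(x, u)`.
#' @export
simulate_example1 <- function(env_params, n_per_env,
                              policy = default_training_policy(),
                              variant = c("linear", "nonlinear_main",
                                          "nonlinear_cate"),
                              seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(length(env_params) >= 1L, n_per_env >= 0L)
  set.seed(seed)
  ys <- props <- numeric(0); ts <- integer(0); envs <- character(0)
  X <- matrix(numeric(0), ncol = 3L,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  U <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("u1", "u2")))
  for (i in seq_along(env_params)) {
    p <- env_params[[i]]
    stopifnot(all(c("gamma1", "gamma2", "gamma3", "mu") %in% names(p)))
    u1 <- stats::rnorm(n_per_env); u2 <- stats::rnorm(n_per_env)
    x1 <- p$gamma1 * u1 + stats::rnorm(n_per_env)
    x2 <- p$gamma2 * u2 + stats::rnorm(n_per_env)
    x3 <- p$gamma3 * u1 + stats::rnorm(n_per_env)
    xm <- cbind(x1 = x1, x2 = x2, x3 = x3)
    dr <- draw_treatments(policy, xm)
    eff <- switch(variant,
      linear = ,
      nonlinear_main = 1 + 0.5 * x2 + 0.5 * u1,
      nonlinear_cate = 1 + 0.5 * x2^2 + 0.5 * x2^3 + 0.5 * u1)
    main <- switch(variant,
      linear = u1 + u2 + x2 + x3 + p$mu,
      nonlinear_main = ,
      nonlinear_cate = u1 + x2 + p$mu + u2 - 0.5 * x2 * x3 + x3)
    y <- dr$t * eff + main + stats::rnorm(n_per_env)
    ys <- c(ys, y); ts <- c(ts, dr$t); props <- c(props, dr$prop)
    envs <- c(envs, rep(paste0("e", i), n_per_env))
    X <- rbind(X, xm); U <- rbind(U, cbind(u1 = u1, u2 = u2))
  }
  truth <- if (variant == "nonlinear_cate")
    cate_function("x2", function(xS) 1 + 0.5 * xS[, 1L]^2 + 0.5 * xS[, 1L]^3)
  else
    cate_function("x2", function(xS) 1 + 0.5 * xS[, 1L])
  truth_full <- if (variant == "nonlinear_cate")
    function(x, u) 1 + 0.5 * x[, "x2"]^2 + 0.5 * x[, "x2"]^3 + 0.5 * u[, "u1"]
  else
    function(x, u) 1 + 0.5 * x[, "x2"] + 0.5 * u[, "u1"]
  data <- if (length(ys) == 0L) {
    structure(list(y = numeric(0), x = X, t = integer(0),
                   env = factor(character(0)), prop = numeric(0),
                   space = treatment_space(2L), n = 0L),
              class = "multienv_data")
  } else multienv_data(ys, X, ts, envs, props)
  new_sim_output(data, U, truth, truth_full)
}

#' Simulate a separable-CATE test environment
#'
#' A single-environment sample whose CATE decomposes additively across two
#' independent covariates: `x2, x3 ~ N(0, 1)` independent,
#' `T ~ Bernoulli(0.5)` and
#' `Y = 1 + x2 + x3 + T (1 + 0.5 x2 + 0.8 x3) + eps`. Conditioning the full
#' CATE on `x2` alone gives `1 + 0.5 x2` (the training-environment CATE on
#' the invariant subset), which makes this the canonical fixture for
#' few-shot constrained estimation.
#'
#' @param m Sample size.
#' @param seed Integer seed.
#' @param g_slope Coefficient of `x3` in the treatment effect (default 0.8).
#' @return A `sim_output` with covariates `x2, x3`; `truth` is the full CATE.
#' @export
simulate_separable <- function(m, seed = 1L, g_slope = 0.8) {
  set.seed(seed)
  x2 <- stats::rnorm(m); x3 <- stats::rnorm(m)
  xm <- cbind(x2 = x2, x3 = x3)
  pol <- bernoulli_policy(0.5)
  dr <- draw_treatments(pol, xm)
  eff <- 1 + 0.5 * x2 + g_slope * x3
  y <- 1 + x2 + x3 + dr$t * eff + stats::rnorm(m)
  truth <- cate_function(c("x2", "x3"),
                         function(xS) 1 + 0.5 * xS[, 1L] + g_slope * xS[, 2L])
  data <- multienv_data(y, xm, dr$t, rep("tst", m), dr$prop)
  new_sim_output(data, matrix(numeric(0), nrow = m, ncol = 0L), truth,
                 function(x, u) 1 + 0.5 * x[, "x2"] + g_slope * x[, "x3"])
}

#' Simulate a micro-randomized-trial-like multi-user fixture
#'
#' Emulates the structure of a mobile-health micro-randomized trial: each
#' user is an environment; at every decision point four treatment-effect
#' features are observed (a bucketized decision time `db` in 0..4, a binary
#' application-engagement indicator `ae`, a 3-level location code `lc` and a
#' binary step-count variation indicator `vi`) together with three
#' baseline-only features (`steps30`, `stepsday`, `temp`); treatment is a
#' binary "deliver suggestion" decision randomized with a fixed probability;
#' and the outcome follows the linear working model
#' `Y = alpha_u' g(X) + beta_u' f(X) T + eps` with user-specific
#' coefficients.
#'
#' Treatment-effect coefficients named in `invariant_features` are held
#' constant across users; coefficients of the remaining effect features vary
#' across users with standard deviation `beta_sd`, breaking effect-invariance
#' of any subset containing them. Effect features enter the outcome model
#' centered at their population means, so a varying coefficient on one
#' feature leaves the CATE of every subset excluding it invariant (the
#' features are drawn independently).
#'
#' @param n_users Number of users (environments), at least 2.
#' @param traj_len Decision points per user.
#' @param coef_config List with elements `beta_mean` (named numeric, means of
#'   the treatment-effect coefficients over `intercept, db, ae, lc, vi`),
#'   `beta_sd` (across-user sd of the varying coefficients),
#'   `invariant_features` (names among `db, ae, lc, vi` plus `intercept`
#'   whose coefficients are shared), `alpha_sd` (across-user sd of baseline
#'   coefficients) and `rand_prob` (randomization probability, default 0.6).
#' @param seed Integer seed.
#' @return A `sim_output`; `truth` is a per-user list of linear CATE
#'   oracles accessible via `attr(, "per_env")`.
#' @export
simulate_mrt_fixture <- function(n_users, traj_len,
                                 coef_config = list(), seed = 1L) {
  stopifnot(n_users >= 2L, traj_len >= 1L)
  cfg <- utils::modifyList(list(
    beta_mean = c(intercept = 0.3, db = 0.1, ae = -0.2, lc = 0.1, vi = 0.15),
    beta_sd = 0.3,
    invariant_features = c("intercept", "db", "lc", "vi"),
    alpha_sd = 0.3,
    rand_prob = 0.6,
    noise_sd = 1), coef_config)
  set.seed(seed)
  eff_names <- c("intercept", "db", "ae", "lc", "vi")
  base_names <- c("steps30", "stepsday", "temp")
  ## user-specific coefficients; invariant components shared across users
  beta <- matrix(rep(cfg$beta_mean, each = n_users), nrow = n_users,
                 dimnames = list(NULL, eff_names))
  vary <- setdiff(eff_names, cfg$invariant_features)
  for (v in vary) {
    ## cohort-centered deviations: heterogeneity destabilizes the effect
    ## without shifting the cohort-average effect of the feature
    dev <- stats::rnorm(n_users, sd = cfg$beta_sd)
    beta[, v] <- beta[, v] + dev - mean(dev)
  }
  alpha <- matrix(stats::rnorm(n_users * (1 + 4 + 3), sd = cfg$alpha_sd),
                  nrow = n_users,
                  dimnames = list(NULL, c("intercept", "db", "ae", "lc", "vi",
                                          base_names)))
  ys <- props <- numeric(0); ts <- integer(0); envs <- character(0)
  X <- NULL
  pol <- bernoulli_policy(cfg$rand_prob)
  for (u in seq_len(n_users)) {
    db <- sample(0:4, traj_len, replace = TRUE)
    ae <- stats::rbinom(traj_len, 1L, 0.5)
    lc <- sample(0:2, traj_len, replace = TRUE)
    vi <- stats::rbinom(traj_len, 1L, 0.4)
    steps30 <- stats::rnorm(traj_len)
    stepsday <- stats::rnorm(traj_len)
    temp <- stats::rnorm(traj_len)
    xm <- cbind(db = db, ae = ae, lc = lc, vi = vi,
                steps30 = steps30, stepsday = stepsday, temp = temp)
    dr <- draw_treatments(pol, xm)
    ## treatment-effect features are centered at their population means so
    ## that a coefficient varying across users shifts only the CATE of
    ## subsets containing that feature (features are drawn independently)
    fX <- cbind(1, db - 2, ae - 0.5, lc - 1, vi - 0.4)
    gX <- cbind(fX, steps30, stepsday, temp)
    y <- drop(gX %*% alpha[u, ]) + dr$t * drop(fX %*% beta[u, ]) +
      stats::rnorm(traj_len, sd = cfg$noise_sd)
    ys <- c(ys, y); ts <- c(ts, dr$t); props <- c(props, dr$prop)
    envs <- c(envs, rep(sprintf("user%02d", u), traj_len))
    X <- rbind(X, xm)
  }
  data <- multienv_data(ys, X, ts, envs, props)
  bmat <- beta
  center_f <- function(xS) {
    xS <- as.matrix(xS)
    cbind(1, xS[, "db"] - 2, xS[, "ae"] - 0.5, xS[, "lc"] - 1,
          xS[, "vi"] - 0.4)
  }
  truth <- cate_function(c("db", "ae", "lc", "vi"), function(xS) {
    ## pooled oracle: average user's effect
    drop(center_f(xS) %*% colMeans(bmat))
  })
  attr(truth, "per_env") <- lapply(seq_len(n_users), function(u) {
    b <- bmat[u, ]
    function(xS) drop(center_f(xS) %*% b)
  })
  new_sim_output(data, matrix(numeric(0), nrow = length(ys), ncol = 0L),
                 truth,
                 function(x, u) drop(center_f(x[, eff_names[-1],
                                                drop = FALSE]) %*%
                                       colMeans(bmat)))
}
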