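## Semi-synthetic policy evaluation.
##
## A policy cannot be replayed against logged data, so a test environment is
## rebuilt from it: fit a linear outcome model with explicit baseline and
## treatment-effect feature maps, keep the (covariate, residual) pairs, then
## resample those pairs, act with the candidate policy, and reassemble
## outcomes from the fitted coefficients plus the resampled residual. Policy
## values are averages of the reassembled outcomes; comparisons between
## policies share the resampling draws (common random numbers).

#' Per-environment linear outcome model with explicit feature maps
#'
#' Ordinary least squares of `y` on `[g(x), f(x) * t]`, where `g` extracts
#' baseline features (including an intercept) and `f` extracts
#' treatment-effect features.
#'
#' @param env_data A single-environment [multienv_data()].
#' @param f_vars Covariate names entering the treatment-effect features
#'   (an intercept is prepended), default all covariates.
#' @param g_vars Covariate names entering the baseline features (an
#'   intercept is prepended), default all covariates.
#' @return An object of class `"outcome_model_fit"`: `alpha_coef`,
#'   `beta_coef`, `residuals`, `x` (covariate rows paired with residuals),
#'   `f_vars`, `g_vars`.
#' @export
fit_outcome_model <- function(env_data, f_vars = colnames(env_data$x),
                              g_vars = colnames(env_data$x)) {
  stopifnot(all(f_vars %in% colnames(env_data$x)),
            all(g_vars %in% colnames(env_data$x)))
  G <- cbind(`(i)` = 1, env_data$x[, g_vars, drop = FALSE])
  F_ <- cbind(`(i)` = 1, env_data$x[, f_vars, drop = FALSE])
  D <- cbind(G, F_ * env_data$t)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("degenerate design in the outcome model", call. = FALSE)
  cf <- qr.coef(qrD, env_data$y)
  fitted <- drop(D %*% cf)
  structure(list(alpha_coef = cf[seq_len(ncol(G))],
                 beta_coef = cf[ncol(G) + seq_len(ncol(F_))],
                 residuals = env_data$y - fitted,
                 x = env_data$x, f_vars = f_vars, g_vars = g_vars),
            class = "outcome_model_fit")
}

#' @export
print.outcome_model_fit <- function(x, ...) {
  cat(sprintf("<outcome_model_fit> n = %d, treatment features: (i), %s\n",
              length(x$residuals), paste(x$f_vars, collapse = ", ")))
  invisible(x)
}

## internal: draw the shared resampling stream: row indices + action uniforms
value_draws <- function(fit, n_boot, seed) {
  set.seed(seed)
  list(idx = sample.int(length(fit$residuals), n_boot, replace = TRUE),
       u = stats::runif(n_boot))
}

## internal: value of a policy under a fixed draw stream
value_under_draws <- function(fit, policy, draws) {
  x <- fit$x[draws$idx, , drop = FALSE]
  eps <- fit$residuals[draws$idx]
  G <- cbind(1, x[, fit$g_vars, drop = FALSE])
  F_ <- cbind(1, x[, fit$f_vars, drop = FALSE])
  p1 <- predict(policy, x)[, 2L]
  t_draw <- as.numeric(draws$u < p1)
  mean(drop(G %*% fit$alpha_coef) + drop(F_ %*% fit$beta_coef) * t_draw + eps)
}

#' Residual-bootstrap value of a policy
#'
#' Resamples (covariate, residual) pairs jointly with replacement to
#' `n_boot` observations, draws actions from the policy, reassembles
#' outcomes from the fitted outcome model and averages them.
#'
#' @param fit An [fit_outcome_model()] object.
#' @param policy The policy to evaluate.
#' @param n_boot Number of resampled observations (default 1000).
#' @param seed Integer seed.
#' @return Scalar estimated value.
#' @export
residual_bootstrap_value <- function(fit, policy, n_boot = 1000L, seed = 1L) {
  if (n_boot < 1L) stop("`n_boot` must be at least 1", call. = FALSE)
  value_under_draws(fit, policy, value_draws(fit, n_boot, seed))
}

#' Relative value of a policy against a baseline policy
#'
#' `V(policy) - V(baseline)` with both values computed on the same
#' resampling stream (shared covariate/residual draws and shared action
#' uniforms), so that comparing a policy against itself returns exactly 0.
#'
#' @inheritParams residual_bootstrap_value
#' @param baseline Baseline policy (default: always-control).
#' @return Scalar relative value.
#' @export
relative_value <- function(fit, policy, baseline = constant_policy(0L),
                           n_boot = 1000L, seed = 1L) {
  if (n_boot < 1L) stop("`n_boot` must be at least 1", call. = FALSE)
  draws <- value_draws(fit, n_boot, seed)
  value_under_draws(fit, policy, draws) -
    value_under_draws(fit, baseline, draws)
}

#' Leave-one-environment-out policy comparison
#'
#' For each environment in turn: hold it out, learn an effect-invariant
#' policy and a full-covariate-pool CATE argmax policy on the remaining
#' environments, rebuild the held-out environment with
#' [fit_outcome_model()], and score the effect-invariant, full-set and
#' uniformly random policies by [relative_value()]. Returns the
#' per-environment table and a two-sided paired signed-rank p-value
#' comparing the effect-invariant and full-set policies.
#'
#' @param data A [multienv_data()] with at least 3 environments.
#' @param f_vars Treatment-effect feature names (tested pool and outcome
#'   model features); default all covariates.
#' @param g_vars Baseline feature names; default all covariates.
#' @param alpha Significance level for the subset tests.
#' @param method `"wald"` (default) or `"dr"` for the subset tests.
#' @param n_boot Resample size per evaluation.
#' @param seed Integer seed.
#' @param config Extra options forwarded to [learn_einv_policy()].
#' @return An object of class `"loeo_result"`: `table` (data frame with one
#'   row per held-out environment and columns `einv`, `full`, `random`,
#'   `fallback`), `p_value` (signed-rank, einv vs full) and `wins`
#'   (environments where einv strictly beats full).
#' @export
leave_one_env_out <- function(data, f_vars = colnames(data$x),
                              g_vars = colnames(data$x), alpha = 0.05,
                              method = "wald", n_boot = 1000L, seed = 1L,
                              config = list()) {
  envs <- levels(data$env)
  if (length(envs) < 3L)
    stop("leave-one-environment-out needs at least 3 environments",
         call. = FALSE)
  rows <- vector("list", length(envs))
  for (i in seq_along(envs)) {
    e <- envs[i]
    train <- subset_records(data, data$env != e)
    test <- subset_records(data, data$env == e)
    cfg <- utils::modifyList(list(seed = seed + i, screen = FALSE,
                                  max_pool = length(f_vars)), config)
    ## restrict the tested pool to the treatment-effect features
    train_f <- multienv_data(train$y, train$x[, f_vars, drop = FALSE],
                             train$t, as.character(train$env), train$prop,
                             train$space)
    zs <- learn_einv_policy(train_f, test$x[, f_vars, drop = FALSE],
                            alpha = alpha, method = method, config = cfg)
    full_cate <- pooled_cate_fit(train_f, f_vars,
                                 learner = cfg$cate_learner %||% "linear",
                                 seed = cfg$seed)
    full_policy <- policy_from_cate(full_cate)
    einv_policy <- lift_policy(zs$policy, f_vars)
    full_policy <- lift_policy(full_policy, f_vars)
    fit <- fit_outcome_model(test, f_vars = f_vars, g_vars = g_vars)
    rows[[i]] <- data.frame(
      env = e,
      einv = relative_value(fit, einv_policy, n_boot = n_boot,
                            seed = seed + 1000L + i),
      full = relative_value(fit, full_policy, n_boot = n_boot,
                            seed = seed + 1000L + i),
      random = relative_value(fit, uniform_policy(data$space),
                              n_boot = n_boot, seed = seed + 1000L + i),
      fallback = zs$fallback_used,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  p <- if (all(tab$einv == tab$full)) 1  # identical policies: no evidence
  else suppressWarnings(stats::wilcox.test(tab$einv, tab$full,
                                           paired = TRUE,
                                           exact = FALSE)$p.value)
  structure(list(table = tab, p_value = p,
                 wins = sum(tab$einv > tab$full)),
            class = "loeo_result")
}

## internal: adapt a policy trained on a covariate subset to full matrices
lift_policy <- function(policy, vars) {
  new_policy(function(x) {
    x <- as.matrix(x)
    if (!is.null(colnames(x)) && all(vars %in% colnames(x)))
      x <- x[, vars, drop = FALSE]
    predict(policy, x)
  }, k = policy$k, support_subset = policy$support_subset,
  label = policy$label)
}

#' @export
print.loeo_result <- function(x, ...) {
  cat(sprintf("<loeo_result> einv beats full in %d/%d environments; signed-rank p = %.4g\n",
              x$wins, nrow(x$table), x$p_value))
  print(x$table, row.names = FALSE)
  invisible(x)
}
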