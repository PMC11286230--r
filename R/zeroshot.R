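## Zero-shot policy learning through effect-invariance.
##
## Pipeline: Lasso-screen the covariates, test every subset of the screened
## pool for effect-invariance, fit a pooled CATE on each accepted subset,
## turn each CATE into its argmax policy, score each candidate on the test
## environment's covariates, and return the policy of the best-scoring
## subset. Only covariates are needed from the test environment.

#' Lasso screening of treatment-effect modifiers
#'
#' L1-penalized regression of cross-fitted DR pseudo-outcomes on all
#' covariates (pooled over environments). Variables with nonzero
#' coefficients at the cross-validated penalty survive, capped at `max_pool`
#' by coefficient magnitude. The empty subset always remains testable
#' regardless of the pool.
#'
#' @param data A [multienv_data()] with binary treatment.
#' @param max_pool Maximum pool size (default: all covariates).
#' @param seed Integer seed (controls the nuisance split and CV folds).
#' @param nuisance Outcome-nuisance spec for the pseudo-outcomes.
#' @return Character vector of surviving covariate names (possibly empty).
#' @export
screen_variables <- function(data, max_pool = ncol(data$x), seed = 1L,
                             nuisance = list(outcome = "linear")) {
  stopifnot(ncol(data$x) >= 1L)
  if (ncol(data$x) == 1L) return(colnames(data$x))
  o <- cross_fit_pseudo_outcomes(data, nuisance, seed = seed)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(data$x, o, nfolds = 5L)
  cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1L, 1L]
  if (all(cf == 0))   # fall back to the less parsimonious rule
    cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1L, 1L]
  ## drop coefficients that are negligible next to the strongest signal
  ## (the heavy-tailed pseudo-outcomes make the CV curve flat, so the
  ## penalty alone separates signal from noise poorly)
  keep <- names(cf)[cf != 0 & abs(cf) >= 0.1 * max(abs(cf))]
  keep <- keep[order(abs(cf[keep]), decreasing = TRUE)]
  utils::head(keep, max_pool)
}

## internal: subsets of `pool` in size-then-lexicographic order, incl. empty
enumerate_subsets <- function(pool) {
  subsets <- list(character(0))
  for (size in seq_along(pool)) {
    combos <- utils::combn(sort(pool), size, simplify = FALSE)
    subsets <- c(subsets, combos)
  }
  subsets
}

#' Test every subset of a covariate pool for effect-invariance
#'
#' Runs the chosen e-invariance test on every subset of `pool` (including
#' the empty subset) at level `alpha`. Each subset is its own null
#' hypothesis; no multiple-testing correction is applied, and all
#' non-rejected subsets are returned as accepted.
#'
#' @param data A [multienv_data()].
#' @param alpha Significance level per subset.
#' @param method `"wald"` or `"dr"`.
#' @param pool Character vector of candidate covariate names.
#' @param config Options forwarded to the tests ([dr_einv_test()] config;
#'   `pi_tilde` for the Wald test).
#' @return An object of class `"einv_set_collection"`: list with `accepted`
#'   (list of accepted subsets), `results` (every `subset_test_result`),
#'   `alpha`, `method`, `screened_pool`.
#' @export
enumerate_and_test <- function(data, alpha = 0.05,
                               method = c("wald", "dr"),
                               pool = colnames(data$x), config = list()) {
  method <- match.arg(method)
  subsets <- enumerate_subsets(pool)
  results <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    S <- subsets[[i]]
    results[[i]] <- if (method == "wald")
      wald_einv_test(data, S, alpha,
                     pi_tilde = config$pi_tilde %||% bernoulli_policy(0.5))
    else dr_einv_test(data, S, alpha, config)
  }
  accepted <- results[!vapply(results, `[[`, logical(1), "reject")]
  structure(list(accepted = lapply(accepted, `[[`, "subset"),
                 results = results, alpha = alpha, method = method,
                 screened_pool = pool),
            class = "einv_set_collection")
}

#' @export
print.einv_set_collection <- function(x, ...) {
  cat(sprintf("<einv_set_collection> %d/%d subsets accepted at alpha = %g (%s test)\n",
              length(x$accepted), length(x$results), x$alpha, x$method))
  for (r in x$results) print(r)
  invisible(x)
}

#' Argmax policy induced by a CATE function
#'
#' At each covariate value, the policy spreads its mass uniformly over the
#' treatments maximizing the estimated effect; the baseline treatment
#' competes with effect exactly zero.
#'
#' @param cate A [cate_function()].
#' @param tol Tie tolerance on the effect scale.
#' @return A [new_policy()] supported on `cate$subset`.
#' @export
policy_from_cate <- function(cate, tol = 1e-12) {
  k <- cate$space$k
  t0 <- cate$space$t0
  subset <- cate$subset
  new_policy(function(x) {
    x <- as.matrix(x)
    if (length(subset) > 0L && is.null(colnames(x)) &&
        ncol(x) == length(subset))
      colnames(x) <- subset
    eff <- matrix(0, nrow(x), k)
    for (t in setdiff(0:(k - 1L), t0))
      eff[, t + 1L] <- predict(cate, x, t = t)
    best <- apply(eff, 1L, max)
    win <- abs(eff - best) <= tol
    win / rowSums(win)
  }, k = k, support_subset = subset, label = "argmax(cate)")
}

#' Expected-effect criterion of a candidate subset on test covariates
#'
#' The average, over the test environment's covariate sample, of the
#' estimated effect collected by the candidate policy:
#' `(1/m) sum_i sum_t tau_S(x_i^S, t) pi_S(t | x_i)`. Used to rank accepted
#' effect-invariant subsets; identifiable from test covariates alone.
#'
#' @param cate A [cate_function()].
#' @param policy The policy to score (must be supported on `cate$subset`).
#' @param x_test Covariate matrix from the test environment.
#' @return Scalar criterion value.
#' @export
subset_selection_criterion <- function(cate, policy, x_test) {
  x_test <- as.matrix(x_test)
  if (nrow(x_test) == 0L)
    stop("`x_test` must contain at least one record", call. = FALSE)
  p <- predict(policy, x_test)
  k <- cate$space$k
  val <- 0
  for (t in setdiff(0:(k - 1L), cate$space$t0))
    val <- val + mean(predict(cate, x_test, t = t) * p[, t + 1L])
  val
}

#' Zero-shot effect-invariant policy learning
#'
#' Full pipeline: screen covariates, enumerate and test subsets, fit a
#' pooled CATE per accepted subset, build its argmax policy, score it on the
#' test covariates and return the best subset's policy. When no subset is
#' accepted the constant policy maximizing the pooled average treatment
#' effect is returned and flagged.
#'
#' @param train A [multienv_data()] of training environments.
#' @param x_test Covariate matrix from the (outcome-free) test environment;
#'   columns must match the training covariates.
#' @param alpha Significance level for the subset tests.
#' @param method `"wald"` or `"dr"`.
#' @param config Options: `seed` (default 1), `max_pool`, `screen`
#'   (default `TRUE` when more than 3 covariates), `cate_learner`
#'   (`"linear"` or `"forest"`), `cate_nuisance`, plus test options
#'   forwarded to [enumerate_and_test()].
#' @return An object of class `"zero_shot_result"`: `s_star`, `policy`,
#'   `criterion` (named per accepted subset), `fallback_used`, `tests`,
#'   `cates`.
#' @export
learn_einv_policy <- function(train, x_test, alpha = 0.05,
                              method = c("wald", "dr"), config = list()) {
  method <- match.arg(method)
  x_test <- as.matrix(x_test)
  stopifnot(identical(colnames(x_test), colnames(train$x)))
  cfg <- utils::modifyList(list(seed = 1L, max_pool = ncol(train$x),
                                screen = ncol(train$x) > 3L,
                                cate_learner = "linear",
                                cate_nuisance = list(outcome = "linear")),
                           config)
  pool <- if (isTRUE(cfg$screen))
    screen_variables(train, cfg$max_pool, seed = cfg$seed,
                     nuisance = cfg$cate_nuisance)
  else utils::head(colnames(train$x), cfg$max_pool)
  tests <- enumerate_and_test(train, alpha, method, pool, cfg)
  if (length(tests$accepted) == 0L) {
    ate <- mean(cross_fit_pseudo_outcomes(train, cfg$cate_nuisance,
                                          seed = cfg$seed))
    t_best <- if (ate > 0) 1L else 0L
    return(structure(list(s_star = NULL,
                          policy = constant_policy(t_best, train$space),
                          criterion = numeric(0), fallback_used = TRUE,
                          tests = tests, cates = list()),
                     class = "zero_shot_result"))
  }
  cates <- lapply(tests$accepted, function(S)
    pooled_cate_fit(train, S, learner = cfg$cate_learner,
                    nuisance = cfg$cate_nuisance, seed = cfg$seed))
  policies <- lapply(cates, policy_from_cate)
  crit <- vapply(seq_along(cates), function(i)
    subset_selection_criterion(cates[[i]], policies[[i]], x_test),
    numeric(1))
  names(crit) <- vapply(tests$accepted, function(S)
    if (length(S) == 0L) "{}" else paste(S, collapse = ","), character(1))
  ## seeded uniform tie-break among criterion maximizers
  top <- which(crit >= max(crit) - 1e-12)
  set.seed(cfg$seed)
  pick <- if (length(top) > 1L) sample(top, 1L) else top
  structure(list(s_star = tests$accepted[[pick]], policy = policies[[pick]],
                 criterion = crit, fallback_used = FALSE, tests = tests,
                 cates = cates),
            class = "zero_shot_result")
}

#' @export
print.zero_shot_result <- function(x, ...) {
  if (x$fallback_used) {
    cat("<zero_shot_result> no subset accepted; constant fallback policy\n")
  } else {
    cat(sprintf("<zero_shot_result> S* = {%s}; criterion:\n",
                paste(x$s_star, collapse = ", ")))
    print(round(x$criterion, 4))
  }
  invisible(x)
}
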