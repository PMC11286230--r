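#' Treatment space
#'
#' A finite set of treatment levels `0, ..., k - 1` together with a baseline
#' level `t0` that serves as the reference point of all treatment-effect
#' contrasts. All CATE functions in this package are contrasts against `t0`,
#' so they vanish identically at `t0`.
#'
#' @param k Number of treatment levels (at least 2).
#' @param t0 Baseline treatment level, an integer in `0:(k - 1)`. Default 0.
#'
#' @return An object of class `"treatment_space"` with elements `k` and `t0`.
#' @export
#' @examples
#' treatment_space(2)
treatment_space <- function(k, t0 = 0L) {
  k <- as.integer(k)
  t0 <- as.integer(t0)
  if (length(k) != 1L || is.na(k) || k < 2L)
    stop("`k` must be a single integer >= 2", call. = FALSE)
  if (length(t0) != 1L || is.na(t0) || t0 < 0L || t0 >= k)
    stop("`t0` must lie in 0:(k - 1)", call. = FALSE)
  structure(list(k = k, t0 = t0), class = "treatment_space")
}

#' Multi-environment bandit log
#'
#' Container for logged decisions collected across several environments
#' (users, sites, experimental regimes). Each record carries an outcome, the
#' treatment that was taken, the environment it came from, the covariates
#' observed before acting, and the probability with which the logging policy
#' selected the realized treatment (the recorded propensity).
#'
#' Strict positivity of the recorded propensities is required: records with
#' `prop <= 1e-6` are rejected rather than clipped, and missing values in any
#' field are rejected rather than imputed.
#'
#' @param y Numeric outcome vector.
#' @param x Covariate matrix or data frame with named columns (`n` rows).
#' @param t Integer treatment per record (levels in `0:(k - 1)`).
#' @param env Environment label per record (character, factor or integer).
#' @param prop Recorded probability of the realized treatment, in `(0, 1]`.
#' @param space A [treatment_space()]. Default binary with baseline 0.
#'
#' @return An object of class `"multienv_data"`: a list with elements `y`,
#'   `x` (numeric matrix with column names), `t`, `env` (factor), `prop`,
#'   `space`, and `n`.
#' @export
multienv_data <- function(y, x, t, env, prop, space = treatment_space(2L)) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  n <- length(y)
  t <- as.integer(t)
  if (nrow(x) != n || length(t) != n || length(env) != n || length(prop) != n)
    stop("all fields of a multi-environment dataset must have equal length",
         call. = FALSE)
  if (anyNA(y) || anyNA(x) || anyNA(t) || anyNA(env) || anyNA(prop))
    stop("missing values are not allowed in a multi-environment dataset",
         call. = FALSE)
  if (any(prop <= 1e-6) || any(prop > 1))
    stop("recorded propensities must lie in (1e-6, 1] (positivity)",
         call. = FALSE)
  if (any(t < 0L) || any(t >= space$k))
    stop("treatment levels must lie in 0:(k - 1)", call. = FALSE)
  env <- factor(env)
  structure(
    list(y = as.numeric(y), x = x, t = t, env = env,
         prop = as.numeric(prop), space = space, n = n),
    class = "multienv_data"
  )
}

#' @export
print.multienv_data <- function(x, ...) {
  cat(sprintf("<multienv_data> n = %d, d = %d covariates (%s), %d environments, k = %d treatments\n",
              x$n, ncol(x$x), paste(colnames(x$x), collapse = ", "),
              nlevels(x$env), x$space$k))
  invisible(x)
}

#' @export
as.data.frame.multienv_data <- function(x, ...) {
  data.frame(y = x$y, t = x$t, env = as.character(x$env), prop = x$prop,
             x$x, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Subset the records of a multi-environment dataset
#'
#' @param data A [multienv_data()] object.
#' @param idx Integer or logical index into the records.
#' @return A `multienv_data` with the selected records.
#' @export
subset_records <- function(data, idx) {
  multienv_data(data$y[idx], data$x[idx, , drop = FALSE], data$t[idx],
                as.character(data$env)[idx], data$prop[idx], data$space)
}

## ---------------------------------------------------------------- policies

#' Construct a policy
#'
#' A policy maps a covariate vector to a probability vector over the `k`
#' treatment levels. `support_subset` declares the covariates the policy is
#' allowed to depend on; `character(0)` declares a context-free policy.
#'
#' @param prob_fn Function taking an `n x d` covariate matrix (with column
#'   names) and returning an `n x k` matrix of treatment probabilities.
#' @param k Number of treatment levels.
#' @param support_subset Character vector of covariate names the policy
#'   depends on, or `NULL` if unrestricted.
#' @param label Optional human-readable tag.
#'
#' @return An object of class `"policy"`.
#' @export
new_policy <- function(prob_fn, k = 2L, support_subset = NULL, label = NULL) {
  stopifnot(is.function(prob_fn))
  structure(list(prob_fn = prob_fn, k = as.integer(k),
                 support_subset = support_subset, label = label),
            class = "policy")
}

#' Evaluate a policy on covariates
#'
#' @param object A [new_policy()] object.
#' @param x Covariate matrix or data frame (rows = records).
#' @param ... Unused.
#' @return An `n x k` matrix of action probabilities (rows sum to 1).
#' @export
predict.policy <- function(object, x, ...) {
  x <- as.matrix(x)
  p <- object$prob_fn(x)
  if (is.null(dim(p)) || nrow(p) != nrow(x) || ncol(p) != object$k)
    stop("policy returned probabilities of the wrong shape", call. = FALSE)
  p <- unname(as.matrix(p))
  bad <- abs(rowSums(p) - 1) > 1e-12 | apply(p < -1e-15, 1L, any)
  if (any(bad))
    stop("policy returned probabilities that are negative or do not sum to 1",
         call. = FALSE)
  p
}

#' @export
print.policy <- function(x, ...) {
  s <- if (is.null(x$support_subset)) "all covariates"
       else if (length(x$support_subset) == 0L) "none (context-free)"
       else paste(x$support_subset, collapse = ", ")
  cat(sprintf("<policy> k = %d, support: %s%s\n", x$k, s,
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' Policy that always selects a fixed treatment
#'
#' @param t Treatment level to select.
#' @param space A [treatment_space()].
#' @return A context-free [new_policy()] putting mass 1 on `t`.
#' @export
#' @examples
#' predict(constant_policy(0), matrix(rnorm(3), ncol = 1))
constant_policy <- function(t, space = treatment_space(2L)) {
  t <- as.integer(t)
  if (t < 0L || t >= space$k)
    stop("`t` must be a valid treatment level", call. = FALSE)
  k <- space$k
  new_policy(function(x) {
    p <- matrix(0, nrow(x), k)
    p[, t + 1L] <- 1
    p
  }, k = k, support_subset = character(0),
  label = sprintf("always-%d", t))
}

#' Context-free Bernoulli policy (binary treatments)
#'
#' Selects treatment 1 with fixed probability `q` regardless of covariates.
#'
#' @param q Probability of treatment 1, strictly inside (0, 1).
#' @return A context-free [new_policy()] with `k = 2`.
#' @export
bernoulli_policy <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("`q` must lie strictly inside (0, 1)", call. = FALSE)
  new_policy(function(x) cbind(rep(1 - q, nrow(x)), rep(q, nrow(x))),
             k = 2L, support_subset = character(0),
             label = sprintf("bernoulli(%g)", q))
}

#' Uniformly random policy
#'
#' @param space A [treatment_space()].
#' @return A context-free [new_policy()] assigning each level probability 1/k.
#' @export
uniform_policy <- function(space = treatment_space(2L)) {
  k <- space$k
  new_policy(function(x) matrix(1 / k, nrow(x), k), k = k,
             support_subset = character(0), label = "uniform")
}

## ---------------------------------------------------------- CATE functions

#' Construct a CATE function on a covariate subset
#'
#' A conditional average treatment effect function tau(x_S, t) measured
#' relative to the baseline treatment `t0`, so that `tau(., t0)` is
#' identically zero by construction.
#'
#' @param subset Character vector of covariate names the function depends on
#'   (may be empty: a constant effect).
#' @param fn Function taking an `n x |S|` matrix of subset covariates and
#'   returning the effect of treatment 1 versus baseline (binary case), or a
#'   function `(xS, t)` returning effects for level `t` (multi-level).
#' @param space A [treatment_space()].
#' @return An object of class `"cate_function"`.
#' @export
cate_function <- function(subset, fn, space = treatment_space(2L)) {
  structure(list(subset = subset, fn = fn, space = space),
            class = "cate_function")
}

#' Evaluate a CATE function
#'
#' @param object A [cate_function()].
#' @param x Covariate matrix (full or subset columns; subset columns are
#'   extracted by name when present).
#' @param t Treatment level at which to evaluate (scalar). Effects at the
#'   baseline level are exactly zero.
#' @param ... Unused.
#' @return Numeric vector of effects, one per row of `x`.
#' @export
predict.cate_function <- function(object, x, t = 1L, ...) {
  x <- as.matrix(x)
  if (length(object$subset) > 0L && !is.null(colnames(x)) &&
      all(object$subset %in% colnames(x)))
    x <- x[, object$subset, drop = FALSE]
  if (t == object$space$t0) return(rep(0, nrow(x)))
  fa <- formals(object$fn)
  if (length(fa) >= 2L) object$fn(x, t) else object$fn(x)
}

#' @export
print.cate_function <- function(x, ...) {
  cat(sprintf("<cate_function> subset: {%s}\n",
              paste(x$subset, collapse = ", ")))
  invisible(x)
}

## -------------------------------------------------------- pseudo-outcomes

#' Doubly robust pseudo-outcome (binary treatment)
#'
#' The augmented inverse-propensity-weighted transform
#' \deqn{O = \bar\mu(x,1) - \bar\mu(x,0)
#'       + 1\{t=1\}\frac{y - \bar\mu(x,1)}{\bar\pi(1|x)}
#'       - 1\{t=0\}\frac{y - \bar\mu(x,0)}{1 - \bar\pi(1|x)},}
#' whose conditional mean given any covariate subset equals the CATE on that
#' subset whenever at least one of the two nuisance models (outcome model
#' \eqn{\bar\mu} or propensity model \eqn{\bar\pi}) is correct (double
#' robustness).
#'
#' @param y Outcome vector.
#' @param t Treatment vector in `{0, 1}`.
#' @param mu1,mu0 Outcome-model predictions `mu(x, 1)` and `mu(x, 0)` per
#'   record (each record evaluated under its own environment's model).
#' @param p1 Propensity-model probability of treatment 1 per record, strictly
#'   inside `(0, 1)`.
#' @return Numeric vector of pseudo-outcomes.
#' @export
pseudo_outcome <- function(y, t, mu1, mu0, p1) {
  if (any(t != 0L & t != 1L))
    stop("pseudo-outcomes support binary treatments only; reduce multi-level ",
         "problems to per-level contrasts against the baseline", call. = FALSE)
  if (any(p1 <= 0) || any(p1 >= 1))
    stop("propensity must lie strictly inside (0, 1) (positivity)",
         call. = FALSE)
  mu1 - mu0 + ifelse(t == 1L, (y - mu1) / p1, -(y - mu0) / (1 - p1))
}

## internal: per-(environment, arm) outcome nuisances
## spec: list(outcome = "linear"|"forest", num_trees)
fit_mu_models <- function(data, spec = list(outcome = "linear"), idx = NULL) {
  if (is.null(idx)) idx <- seq_len(data$n)
  outcome <- spec$outcome %||% "linear"
  num_trees <- spec$num_trees %||% 100L
  models <- list()
  for (e in levels(data$env)) {
    for (arm in 0:1) {
      sel <- idx[as.character(data$env)[idx] == e & data$t[idx] == arm]
      if (length(sel) < 2L)
        stop(sprintf("environment '%s' has fewer than 2 records in arm %d",
                     e, arm), call. = FALSE)
      xd <- data$x[sel, , drop = FALSE]
      yv <- data$y[sel]
      key <- paste(e, arm, sep = ".")
      if (outcome == "forest") {
        df <- data.frame(.y = yv, xd, check.names = FALSE)
        fit <- ranger::ranger(
          dependent.variable.name = ".y", data = df,
          num.trees = num_trees, num.threads = 1L,
          seed = (spec$seed %||% 1L))
        models[[key]] <- local({
          f <- fit
          function(xnew) predict(f, data = as.data.frame(xnew),
                                 num.threads = 1L)$predictions
        })
      } else if (outcome == "smooth") {
        df <- data.frame(.y = yv, xd)
        vars <- colnames(df)[-1L]
        nuniq <- vapply(vars, function(v) length(unique(df[[v]])), integer(1))
        terms <- ifelse(nuniq > 10L, sprintf("s(%s)", vars), vars)
        form <- stats::as.formula(paste(".y ~",
                                        paste(terms, collapse = " + ")))
        fit <- mgcv::gam(form, data = df)
        models[[key]] <- local({
          f <- fit
          vn <- vars
          function(xnew) {
            nd <- as.data.frame(as.matrix(xnew))
            names(nd) <- vn
            as.numeric(stats::predict(f, newdata = nd))
          }
        })
      } else if (outcome == "linear") {
        X <- cbind(1, xd)
        cf <- qr.coef(qr(X), yv)
        cf[is.na(cf)] <- 0
        models[[key]] <- local({
          b <- cf
          function(xnew) drop(cbind(1, as.matrix(xnew)) %*% b)
        })
      } else stop("unknown outcome nuisance spec: ", outcome, call. = FALSE)
    }
  }
  models
}

## internal: evaluate per-record mu(x, arm) under each record's own environment
predict_mu <- function(models, env, x, arm) {
  out <- numeric(nrow(x))
  for (e in unique(as.character(env))) {
    sel <- as.character(env) == e
    out[sel] <- models[[paste(e, arm, sep = ".")]](x[sel, , drop = FALSE])
  }
  out
}

## internal: cross-fitted DR pseudo-outcomes using known recorded propensities
cross_fit_pseudo_outcomes <- function(data, spec = list(outcome = "linear"),
                                      seed = 1L) {
  halves <- split_sample(data, fraction = 0.5, seed = seed)
  o <- numeric(data$n)
  p1 <- ifelse(data$t == 1L, data$prop, 1 - data$prop)
  for (side in 1:2) {
    fit_idx <- if (side == 1L) halves$idx1 else halves$idx2
    eval_idx <- if (side == 1L) halves$idx2 else halves$idx1
    models <- fit_mu_models(data, spec, idx = fit_idx)
    mu1 <- predict_mu(models, data$env[eval_idx],
                      data$x[eval_idx, , drop = FALSE], 1L)
    mu0 <- predict_mu(models, data$env[eval_idx],
                      data$x[eval_idx, , drop = FALSE], 0L)
    o[eval_idx] <- pseudo_outcome(data$y[eval_idx], data$t[eval_idx],
                                  mu1, mu0, p1[eval_idx])
  }
  o
}

## ------------------------------------------------------- pooled CATE fit

#' Pooled CATE estimation on a covariate subset
#'
#' Estimates the treatment-effect function tau_S(x_S, 1) by pooling records
#' from all training environments: doubly robust pseudo-outcomes are built
#' with cross-fitted outcome nuisances (recorded propensities are used as the
#' known propensity model) and regressed on the subset covariates.
#'
#' Pooling is justified when `S` is effect-invariant: the per-environment
#' CATE functions on `S` then coincide, and the pooled regression estimates
#' that common function.
#'
#' @param data A [multienv_data()] with binary treatment.
#' @param subset Character vector of covariate names (may be empty, giving a
#'   constant-effect estimate).
#' @param learner Final-stage regression of pseudo-outcomes on `x_S`:
#'   `"linear"` (default) or `"forest"`.
#' @param nuisance Outcome-nuisance spec passed to the internal per-arm
#'   fits: a list with elements `outcome` (`"linear"` or `"forest"`) and
#'   optionally `num_trees`.
#' @param seed Integer seed controlling the nuisance cross-fitting split.
#' @return A [cate_function()] on `subset` whose value at the baseline
#'   treatment is exactly zero.
#' @export
pooled_cate_fit <- function(data, subset, learner = c("linear", "forest"),
                            nuisance = list(outcome = "linear"), seed = 1L) {
  learner <- match.arg(learner)
  if (data$space$k != 2L)
    stop("pooled_cate_fit supports binary treatments", call. = FALSE)
  if (length(unique(data$t)) < 2L)
    stop("degenerate design: dataset contains a single treatment arm",
         call. = FALSE)
  stopifnot(all(subset %in% colnames(data$x)))
  o <- cross_fit_pseudo_outcomes(data, nuisance, seed = seed)
  xs <- data$x[, subset, drop = FALSE]
  if (length(subset) == 0L) {
    est <- mean(o)
    fn <- function(xnew) rep(est, nrow(as.matrix(xnew)))
  } else if (learner == "linear") {
    X <- cbind(1, xs)
    cf <- qr.coef(qr(X), o)
    cf[is.na(cf)] <- 0
    fn <- local({
      b <- cf
      function(xnew) drop(cbind(1, as.matrix(xnew)) %*% b)
    })
  } else {
    df <- data.frame(.o = o, xs, check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = ".o", data = df,
                          num.trees = 200L, num.threads = 1L, seed = seed)
    fn <- local({
      f <- fit
      nm <- subset
      function(xnew) {
        xnew <- as.matrix(xnew)
        colnames(xnew) <- nm
        predict(f, data = as.data.frame(xnew), num.threads = 1L)$predictions
      }
    })
  }
  cate_function(subset, fn, data$space)
}

## internal: null-coalescing helper
`%||%` <- function(a, b) if (is.null(a)) b else a
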