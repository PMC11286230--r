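## Nonparametric effect-invariance test via doubly robust pseudo-outcomes.
##
## Algorithm: split the sample in half (stratified by environment x arm);
## fit per-environment outcome nuisances on the first half; transform the
## second half into DR pseudo-outcomes, whose conditional mean given x_S
## equals the CATE on S whenever one nuisance is correct; then test whether
## that conditional mean is the same in every environment with a
## multi-environment generalised covariance measure (GCM): residualize the
## pseudo-outcome and each reference-coded environment indicator on x_S and
## aggregate the normalized residual products into a chi-squared statistic
## with l - 1 degrees of freedom.

#' Environment-and-arm stratified sample split
#'
#' Randomly partitions the records into two disjoint halves such that every
#' environment and both treatment arms appear in both halves.
#'
#' @param data A [multienv_data()].
#' @param fraction Fraction of records assigned to the first half, in (0, 1).
#' @param seed Integer seed.
#' @return A list with integer index vectors `idx1`, `idx2`.
#' @export
split_sample <- function(data, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly inside (0, 1)", call. = FALSE)
  set.seed(seed)
  ## content-canonical randomization: records are ranked by their values and
  ## a seeded random order is applied to the ranks, so the split is exactly
  ## invariant to record order and to relabeling of the environments
  key <- do.call(order, c(list(data$y, data$t, data$prop),
                          lapply(seq_len(ncol(data$x)),
                                 function(j) data$x[, j])))
  r <- integer(data$n)
  r[key] <- seq_len(data$n)
  u <- sample.int(data$n)
  pos <- u[r]
  strata <- interaction(data$env, data$t, drop = TRUE)
  idx1 <- integer(0)
  for (s in levels(strata)) {
    ids <- which(strata == s)
    if (length(ids) < 2L)
      stop(sprintf("stratum '%s' has fewer than 2 records; cannot split", s),
           call. = FALSE)
    n1 <- max(1L, min(length(ids) - 1L, round(fraction * length(ids))))
    idx1 <- c(idx1, ids[order(pos[ids])][seq_len(n1)])
  }
  idx1 <- sort(idx1)
  list(idx1 = idx1, idx2 = setdiff(seq_len(data$n), idx1))
}

#' Fit nuisance models on the first half of a split
#'
#' Fits one outcome regression per environment and treatment arm on the
#' records indexed by `idx`, and a propensity model. When propensities are
#' declared known (the default), the recorded `prop` mechanism is passed
#' through instead of an estimate.
#'
#' @param data A [multienv_data()].
#' @param idx Record indices of the nuisance-fitting half.
#' @param spec List with elements `outcome` (`"forest"` default, or
#'   `"linear"`), `num_trees` (default 100), `known_propensity` (default
#'   `TRUE`) and `seed`.
#' @return An object of class `"nuisance_models"` with elements `mu`
#'   (callable table indexed by environment and arm), `known_propensity`,
#'   `pi_model` (when estimated) and `fit_indices`.
#' @export
fit_nuisances <- function(data, idx,
                          spec = list(outcome = "forest",
                                      known_propensity = TRUE)) {
  spec$outcome <- spec$outcome %||% "forest"
  known <- spec$known_propensity %||% TRUE
  mu <- fit_mu_models(data, spec, idx = idx)
  pi_model <- NULL
  if (!known) {
    df <- data.frame(.t = data$t[idx], data$x[idx, , drop = FALSE],
                     check.names = FALSE)
    fit <- stats::glm(.t ~ ., family = stats::binomial(), data = df)
    pi_model <- local({
      f <- fit
      function(xnew) {
        p <- stats::predict(f, newdata = as.data.frame(xnew),
                            type = "response")
        pmin(pmax(p, 1e-3), 1 - 1e-3)
      }
    })
  }
  structure(list(mu = mu, known_propensity = known, pi_model = pi_model,
                 fit_indices = idx),
            class = "nuisance_models")
}

## internal: pseudo-outcomes for the records in `idx` under fitted nuisances
nuisance_pseudo_outcomes <- function(data, nuis, idx) {
  x <- data$x[idx, , drop = FALSE]
  mu1 <- predict_mu(nuis$mu, data$env[idx], x, 1L)
  mu0 <- predict_mu(nuis$mu, data$env[idx], x, 0L)
  p1 <- if (nuis$known_propensity)
    ifelse(data$t[idx] == 1L, data$prop[idx], 1 - data$prop[idx])
  else nuis$pi_model(x)
  pseudo_outcome(data$y[idx], data$t[idx], mu1, mu0, p1)
}

## internal: regress `y` on `xS` and return predictions on the same records.
## "smooth" fits an additive spline model (linear in covariates with few
## distinct values); forest predictions are out-of-bag (honest residuals);
## linear uses the least-squares fit. Zero-column xS regresses on the mean.
regress_on_subset <- function(y, xS, spec = "smooth", num_trees = 100L,
                              seed = 1L, weights = NULL) {
  xS <- as.matrix(xS)
  if (ncol(xS) == 0L) {
    m <- if (is.null(weights)) mean(y) else stats::weighted.mean(y, weights)
    return(rep(m, length(y)))
  }
  if (spec == "smooth") {
    df <- data.frame(.y = y, xS)
    vars <- colnames(df)[-1L]
    nuniq <- vapply(vars, function(v) length(unique(df[[v]])), integer(1))
    terms <- ifelse(nuniq > 10L, sprintf("s(%s)", vars), vars)
    form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    return(as.numeric(stats::fitted(
      mgcv::gam(form, data = df, weights = weights))))
  }
  if (spec == "linear") {
    X <- cbind(1, xS)
    w <- if (is.null(weights)) rep(1, length(y)) else weights
    cf <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
    cf[is.na(cf)] <- 0
    drop(X %*% cf)
  } else if (spec == "forest") {
    df <- data.frame(.y = y, xS, check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = num_trees, num.threads = 1L,
                          seed = seed, oob.error = TRUE,
                          case.weights = weights)
    pred <- fit$predictions
    ## rare records never out-of-bag: fall back to in-bag prediction
    nas <- is.na(pred)
    if (any(nas))
      pred[nas] <- predict(fit, data = df[nas, , drop = FALSE],
                           num.threads = 1L)$predictions
    pred
  } else stop("unknown regression spec: ", spec, call. = FALSE)
}

#' Multi-environment weighted conditional mean-equality (GCM) test
#'
#' Tests whether `E[o | xS]` is the same across environments. The
#' pseudo-outcome `o` is residualized on `xS` with a pooled regression and
#' each of the `l - 1` reference-coded environment indicators is
#' residualized on `xS`; the per-record residual products are averaged,
#' studentized, and aggregated into `T = n rbar' Sigma^{-1} rbar`, compared
#' against chi-squared with `l - 1` degrees of freedom.
#'
#' The plain residual-product average has no power against conditional-mean
#' differences that change sign across the covariate range (a slope
#' difference between environments integrates to zero). The weighted
#' variant (default) therefore multiplies each product by an estimated
#' sign-weight function of `x_S`: the products are smoothed against `x_S`
#' on one cross-fitting fold, and the sign of that fit weights the products
#' of the other fold. The weight is a function of `x_S` fit on independent
#' records, so the null distribution is unaffected, while sign-varying
#' differences no longer cancel.
#'
#' @param o Numeric vector (pseudo-outcome per record).
#' @param xS Matrix of subset covariates (possibly zero columns).
#' @param env Environment labels (at least 2 distinct).
#' @param regression Regression class for the residualizations:
#'   `"smooth"` (default; additive spline fit), `"forest"` (out-of-bag
#'   predictions) or `"linear"`.
#' @param num_trees Trees per forest (forest regression only).
#' @param seed Integer seed (forests and the weight cross-fitting split).
#' @param weights Optional record weights passed to the residualizing
#'   regressions (hook for externally weighted variants).
#' @param weight_fn `"none"` (default; plain residual-product test) or
#'   `"estimated"` (cross-fitted sign weight; better power against
#'   sign-varying alternatives, at the cost of a finite-sample level
#'   inflation under heavy-tailed pseudo-outcomes — see the methods
#'   vignette).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
gcm_mean_equality_test <- function(o, xS, env,
                                   regression = c("smooth", "forest",
                                                  "linear"),
                                   num_trees = 100L, seed = 1L,
                                   weights = NULL,
                                   weight_fn = c("none", "estimated")) {
  regression <- match.arg(regression)
  weight_fn <- match.arg(weight_fn)
  env <- factor(env)
  l <- nlevels(env)
  if (l < 2L)
    stop("at least 2 environments are required", call. = FALSE)
  if (l > length(env) - 1L)
    stop("degenerate environment column", call. = FALSE)
  xS <- as.matrix(xS)
  n <- length(o)
  res_o <- o - regress_on_subset(o, xS, regression, num_trees, seed, weights)
  if (ncol(xS) == 0L) weight_fn <- "none"
  set.seed(seed)
  foldA <- sample.int(n, n %/% 2L)
  inA <- seq_len(n) %in% foldA
  R <- matrix(0, n, l - 1L)
  for (j in 2:l) {
    z <- as.numeric(env == levels(env)[j])
    res_z <- z - regress_on_subset(z, xS, regression, num_trees,
                                   seed + j, weights)
    prod_j <- res_o * res_z
    if (weight_fn == "estimated") {
      ## cross-fitted sign weight: smooth the products against x_S on one
      ## fold, weight the other fold by the sign of the fitted surface
      w <- numeric(n)
      for (side in 1:2) {
        fit_idx <- if (side == 1L) inA else !inA
        smoothed <- regress_with_model(prod_j[fit_idx],
                                       xS[fit_idx, , drop = FALSE],
                                       xS[!fit_idx, , drop = FALSE],
                                       regression, num_trees, seed + 31L * j)
        w[!fit_idx] <- sign(smoothed)
      }
      w[w == 0] <- 1
      R[, j - 1L] <- w * prod_j
    } else {
      R[, j - 1L] <- prod_j
    }
  }
  rbar <- colMeans(R)
  Sigma <- crossprod(R) / n - tcrossprod(rbar)
  Sinv <- tryCatch(solve(Sigma), error = function(e) MASS::ginv(Sigma))
  stat <- max(0, n * drop(t(rbar) %*% Sinv %*% rbar))
  if (sum(abs(Sigma)) < 1e-14) stat <- 0  # exact-fit degenerate case
  df <- l - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

## internal: fit y ~ x on one fold, predict on new rows
regress_with_model <- function(y, x, xnew, spec = "smooth",
                               num_trees = 100L, seed = 1L) {
  x <- as.matrix(x); xnew <- as.matrix(xnew)
  if (spec == "linear") {
    cf <- qr.coef(qr(cbind(1, x)), y)
    cf[is.na(cf)] <- 0
    return(drop(cbind(1, xnew) %*% cf))
  }
  if (spec == "smooth") {
    df <- data.frame(.y = y, x)
    vars <- colnames(df)[-1L]
    nuniq <- vapply(vars, function(v) length(unique(df[[v]])), integer(1))
    terms <- ifelse(nuniq > 10L, sprintf("s(%s)", vars), vars)
    form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    fit <- mgcv::gam(form, data = df)
    nd <- as.data.frame(xnew)
    names(nd) <- vars
    return(as.numeric(stats::predict(fit, newdata = nd)))
  }
  dfr <- data.frame(.y = y, x, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = dfr,
                        num.trees = num_trees, num.threads = 1L, seed = seed)
  predict(fit, data = as.data.frame(xnew), num.threads = 1L)$predictions
}

#' DR-learner test of effect-invariance for a covariate subset
#'
#' Nonparametric counterpart of [wald_einv_test()]: splits the sample, fits
#' outcome nuisances on the first half, transforms the second half into
#' doubly robust pseudo-outcomes and applies the multi-environment GCM to
#' test that their conditional mean given `x_S` does not depend on the
#' environment. Valid without any linearity assumption on the CATE.
#'
#' @param data A [multienv_data()] with binary treatment.
#' @param subset Character vector of covariate names (may be empty).
#' @param alpha Significance level.
#' @param config List of options: `split_fraction` (default 0.5), `seed`
#'   (default 1), `outcome` nuisance class (`"smooth"` default — additive
#'   splines per environment and arm; `"forest"` or `"linear"` also
#'   available), `num_trees` (default 100), `known_propensity` (default
#'   `TRUE`), `gcm_regression` (default `"smooth"`), `gcm_weight`
#'   (`"none"` default for the plain product test, or `"estimated"`).
#' @return A `subset_test_result` with `method = "dr"`.
#' @export
dr_einv_test <- function(data, subset, alpha = 0.05, config = list()) {
  cfg <- utils::modifyList(list(split_fraction = 0.5, seed = 1L,
                                outcome = "smooth", num_trees = 100L,
                                known_propensity = TRUE,
                                gcm_regression = "smooth",
                                gcm_weight = "none"), config)
  if (data$space$k != 2L)
    stop("the DR test supports binary treatments", call. = FALSE)
  stopifnot(all(subset %in% colnames(data$x)))
  halves <- split_sample(data, cfg$split_fraction, cfg$seed)
  nuis <- fit_nuisances(data, halves$idx1,
                        spec = list(outcome = cfg$outcome,
                                    num_trees = cfg$num_trees,
                                    known_propensity = cfg$known_propensity,
                                    seed = cfg$seed))
  o <- nuisance_pseudo_outcomes(data, nuis, halves$idx2)
  xS <- data$x[halves$idx2, subset, drop = FALSE]
  res <- gcm_mean_equality_test(o, xS, data$env[halves$idx2],
                                regression = cfg$gcm_regression,
                                num_trees = cfg$num_trees, seed = cfg$seed,
                                weight_fn = cfg$gcm_weight)
  new_subset_test_result(subset, "dr", res$statistic, res$df, res$p_value,
                         alpha)
}
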