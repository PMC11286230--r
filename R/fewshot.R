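## Few-shot constrained CATE estimation.
##
## Given a small outcome-labeled sample from a test environment and the
## training-environment CATE tau_tr on an effect-invariant subset S, the
## test-environment CATE is estimated under the separability assumption
## tau(x, t) = f(x_S, t) + g(x_N, t) with N the complement of S. The
## invariance constraint E[tau(X, t) | X_S] = tau_tr(x_S, t) pins down f in
## terms of g, leaving the unconstrained problem over g only:
##
##   tau_g(x, t) = tau_tr(x_S, t) - qhat_g(x_S, t) + g(x_N, t),
##
## with qhat_g(x_S, t) an estimate of E[g(X_N, t) | X_S = x_S]. With a
## linear class for g and a linear projector the squared-error DR
## pseudo-outcome loss reduces to least squares on the projected-out
## regressors x_N - E[x_N | x_S].

#' Compose a CATE from a complement-part function and its projection
#'
#' Builds `tau(x, t) = tau_tr(x_S, t) - qhat_g(x_S, t) + g(x_N, t)` for the
#' binary contrast, with linear `g` and a linear projector.
#'
#' @param g_coef Named numeric coefficients of `g` over the complement
#'   covariates `N` (no intercept; an intercept cancels against its own
#'   projection).
#' @param tau_tr Training-environment [cate_function()] on the invariant
#'   subset `S`.
#' @param projector Matrix of linear-projector coefficients: one column per
#'   complement covariate, rows `(intercept, S covariates)`, so that
#'   `qhat(x_S) = cbind(1, x_S) %*% projector` predicts `E[x_N | x_S]`.
#' @param space A [treatment_space()].
#' @return A [cate_function()] over the union of `S` and `N`.
#' @export
tau_from_g <- function(g_coef, tau_tr, projector,
                       space = treatment_space(2L)) {
  S <- tau_tr$subset
  N <- colnames(projector)
  stopifnot(identical(names(g_coef), N),
            nrow(projector) == 1L + length(S))
  all_vars <- union(S, N)
  cate_function(all_vars, function(x) {
    x <- as.matrix(x)
    xs <- x[, S, drop = FALSE]
    xn <- x[, N, drop = FALSE]
    qx <- cbind(1, xs) %*% projector          # E[x_N | x_S] per column
    base <- predict(tau_tr, xs, t = 1L)
    base + drop((xn - qx) %*% g_coef)
  }, space)
}

#' Few-shot constrained CATE fit in a test environment
#'
#' Estimates the test-environment CATE from `m` labeled test records while
#' constraining its conditional mean given the effect-invariant subset `S`
#' to equal the training-environment CATE `tau_tr`. Uses a linear class for
#' the complement part `g`, a linear projector refit on the test sample, and
#' squared-error loss against cross-fitted DR pseudo-outcomes; the
#' constrained problem then has the closed-form solution of a least-squares
#' regression of `O - tau_tr(x_S, 1)` on the projected-out complement
#' covariates `x_N - E[x_N | x_S]`.
#'
#' @param test_data A single-environment [multienv_data()].
#' @param tau_tr Training-environment [cate_function()] on subset `S`.
#' @param seed Integer seed for the pseudo-outcome nuisance split.
#' @param nuisance Outcome-nuisance spec (default linear).
#' @param g_class `"linear"` (default) or `"zero"` (constrain `g` to 0 and
#'   return `tau_tr` unchanged).
#' @return An object of class `"separable_cate_model"`: `subset_S`,
#'   `subset_N`, `g_coef`, `projector`, `tau_tr`, `tau` (the implied
#'   [cate_function()]) and `diagnostics` (residual scale of the projector
#'   fits).
#' @export
few_shot_fit <- function(test_data, tau_tr, seed = 1L,
                         nuisance = list(outcome = "linear"),
                         g_class = c("linear", "zero")) {
  g_class <- match.arg(g_class)
  S <- tau_tr$subset
  N <- setdiff(colnames(test_data$x), S)
  if (length(N) == 0L || g_class == "zero") {
    proj <- matrix(numeric(0), nrow = 1L + length(S), ncol = 0L,
                   dimnames = list(NULL, character(0)))
    tau <- cate_function(colnames(test_data$x), function(x)
      predict(tau_tr, as.matrix(x)[, S, drop = FALSE], t = 1L),
      test_data$space)
    return(structure(list(subset_S = S, subset_N = N,
                          g_coef = stats::setNames(numeric(0), character(0)),
                          projector = proj, tau_tr = tau_tr, tau = tau,
                          diagnostics = list()),
                     class = "separable_cate_model"))
  }
  if (test_data$n < length(N) + length(S) + 2L)
    stop("test sample too small for the linear complement class",
         call. = FALSE)
  o <- cross_fit_pseudo_outcomes(test_data, nuisance, seed = seed)
  xs <- test_data$x[, S, drop = FALSE]
  xn <- test_data$x[, N, drop = FALSE]
  ## linear projector: regress each complement covariate on (1, x_S)
  Xs1 <- cbind(1, xs)
  proj <- qr.coef(qr(Xs1), xn)
  proj[is.na(proj)] <- 0
  proj <- matrix(proj, nrow = ncol(Xs1), dimnames = list(NULL, N))
  r <- xn - Xs1 %*% proj
  qr_r <- qr(r)
  if (qr_r$rank < ncol(r))
    stop("degenerate design: projected complement covariates are collinear",
         call. = FALSE)
  target <- o - predict(tau_tr, xs, t = 1L)
  ## centered-treatment regressor scaling is already inside the DR transform,
  ## so plain least squares solves the pseudo-outcome squared-error problem
  g_coef <- qr.coef(qr_r, target)
  names(g_coef) <- N
  tau <- tau_from_g(g_coef, tau_tr, proj, test_data$space)
  structure(list(subset_S = S, subset_N = N, g_coef = g_coef,
                 projector = proj, tau_tr = tau_tr, tau = tau,
                 diagnostics = list(projector_resid_sd = apply(r, 2L, stats::sd),
                                    pseudo_outcome_sd = stats::sd(o))),
            class = "separable_cate_model")
}

#' @export
print.separable_cate_model <- function(x, ...) {
  cat(sprintf("<separable_cate_model> S = {%s}, N = {%s}\n",
              paste(x$subset_S, collapse = ", "),
              paste(x$subset_N, collapse = ", ")))
  if (length(x$g_coef)) {
    cat("g coefficients:\n"); print(round(x$g_coef, 4))
  }
  invisible(x)
}

#' Argmax policy from a few-shot constrained CATE
#'
#' @param model A fitted [few_shot_fit()] model.
#' @return A [new_policy()] maximizing the implied CATE, uniform over ties.
#' @export
few_shot_policy <- function(model) {
  policy_from_cate(model$tau)
}
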