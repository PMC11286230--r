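# Shared fixtures, generated in code.

# Two hand-picked environment parameter sets whose latent-confounder
# loadings (gamma1, gamma3) differ in sign across environments, so the
# conditional mean of the confounder given x1 or x3 flips slope and every
# subset containing x1 or x3 clearly violates effect-invariance.
fixed_params <- list(
  list(gamma1 = 1,    gamma2 = 1,   gamma3 = 1,    mu = 0),
  list(gamma1 = -1.5, gamma2 = 0.5, gamma3 = -1.5, mu = 1)
)

# Small multi-environment dataset from the three-covariate model.
small_example1 <- function(n_per_env = 500, variant = "linear", seed = 1,
                           params = fixed_params) {
  simulate_example1(params, n_per_env, variant = variant, seed = seed)$data
}

# Dataset whose two environments are exact copies of each other (labels
# differ, records identical): every subset is trivially effect-invariant.
duplicated_env_data <- function(n = 300, seed = 3) {
  sim <- simulate_example1(fixed_params[1], n, seed = seed)
  d <- sim$data
  multienv_data(rep(d$y, 2), rbind(d$x, d$x), rep(d$t, 2),
                rep(c("a", "b"), each = n), rep(d$prop, 2))
}

# Monte-Carlo rejection rate of a test callable over seeded replicates.
rejection_rate <- function(reps, seed0, fn) {
  mean(vapply(seq_len(reps), function(i) fn(seed0 + 17L * i), logical(1)))
}
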