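# Shared fixtures and closed-form oracles used across test files.

# Analytic logistic solution P(t) for a single uncoupled strain.
logistic_closed_form <- function(t, r, K, P0) {
  K * P0 * exp(r * t) / (K + P0 * (exp(r * t) - 1))
}

# Two-strain model with all cross terms zero (decoupled logistics).
decoupled_pair <- function(r_p = 0.5, r_k = 0.6, K = 1e9) {
  glv_model(list(strain_spec("pro", "probiotic", r = r_p, K = K),
                 strain_spec("pat", "pathogen", r = r_k, K = K)))
}

# Random two-strain model within published ranges, for property sweeps.
random_pair <- function(seed) {
  set.seed(seed)
  glv_model(
    list(strain_spec("pro", "probiotic", r = runif(1, 0.05, 1.5), K = 1e9),
         strain_spec("pat", "pathogen", r = runif(1, 0.05, 1.5), K = 1e9)),
    interaction_set(beta = matrix(runif(1, 0, 2), 1, 1),
                    delta = matrix(runif(1, 0, 2), 1, 1)))
}

# Small ABM setup for fast behavioural tests.
small_grid <- function(...) abm_grid(width = 20, height = 20, ...)
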