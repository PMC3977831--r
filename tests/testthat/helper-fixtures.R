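# Shared fixtures: a default generator on the [0, 1] intensity scale and a
# reduced sampler configuration for simulation-heavy checks.

default_gen <- function() psy_params(m = 0.5, w = 0.2, lam = 0.02, gamma = 0.5)

# reduced sampler sizes keep simulation checks fast; effects asserted below
# are medians over many pairs, which tolerate the extra Monte Carlo noise
test_config <- function() sir_config(n_proposals = 5000, n_final = 500)

# a small fixed dataset with good coverage of asymptotes and rise
fixed_data <- function(condition = "fixed") {
  block_data(intensity = c(0.15, 0.35, 0.45, 0.55, 0.65, 0.85),
             k = c(26, 29, 34, 42, 47, 49),
             n = rep(50, 6), condition = condition)
}

quiet <- function(expr) suppressWarnings(expr)
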