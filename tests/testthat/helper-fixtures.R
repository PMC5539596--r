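# Shared fixtures, all built in code.

aldehyde_law <- function() psychophysical_law(5.6, -5.6)
ester_law <- function() psychophysical_law(1.4, -2.7)

# noiseless panel config: single assessor, continuous ratings
exact_panel_config <- function(family = "aldehydes", seed = 1L, ...) {
  panel_sim_config(family, assessor_sd = 0, n_assessors = 1L,
                   oirs_resolution = 0, seed = seed, ...)
}

# literal transcriptions of the binary and ternary vector sums, used as
# independent oracles for the n-component generalization
binary_vector_sum <- function(a, b, cab) {
  sqrt(a^2 + b^2 + 2 * cab * a * b)
}
ternary_vector_sum <- function(a, b, c, cab, cac, cbc) {
  sqrt(a^2 + b^2 + c^2 + 2 * cab * a * b + 2 * cac * a * c + 2 * cbc * b * c)
}

# rank-tolerant linear least-squares concentration oracle for sensor data
linear_ls_oracle <- function(db) {
  X <- cbind(1, db$signals)
  B <- apply(db$concentrations, 2, function(y) {
    cf <- stats::coef(stats::lm.fit(X, y))
    ifelse(is.na(cf), 0, cf)
  })
  pmax(X %*% B, 0)
}

# small but accurate estimator configuration for pipeline tests
fast_estimator_config <- function(seed = 1L) {
  estimator_config(hidden_layers = 2L, neurons_per_layer = 12L,
                   max_iterations = 1500L, n_starts = 2L, seed = seed)
}
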