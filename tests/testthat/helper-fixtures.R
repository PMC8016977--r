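# shared fixtures and independent oracles

small_config <- function(seed = 1, ...) {
  sim_config(n_species = 40, n_plots = 2, seed = seed, ...)
}

# closed-form OLS via normal equations, independent of lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  a <- sxy / sxx
  c(slope = a, intercept = mean(y) - a * mean(x))
}

# a hand-built MASS-style run: standards at known positions, no unknowns
standards_run <- function(deltas, positions,
                          names = rep("USGS-40", length(deltas))) {
  tibble::tibble(
    sequence_no = as.integer(positions),
    sample_type = "standard",
    sample_id = names,
    standard_name = names,
    raw_delta = deltas,
    facility = "CSIRO"
  )
}
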