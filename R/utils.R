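# internal helpers

# Deterministic child seed from a master seed and a character tag, so each
# simulated artifact consumes its own RNG stream and adding a new artifact
# never perturbs existing ones. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Truncated normal via inverse-CDF so draw count is deterministic.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (lower >= upper) abort("truncation bounds must satisfy lower < upper")
  p <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(p, mean, sd)
}

# Truncate (not round) a percentage to one decimal place.
truncate1 <- function(x) floor(x * 10 + 1e-9) / 10

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_fraction <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single number in [0, 1]"))
  }
  invisible(x)
}
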