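# Internal numerical helpers shared across modules.

# Upper 100*alpha% standard-normal quantile (z_alpha), used throughout for
# one-sided tests at level alpha and two-sided 100*(1-2*alpha)% intervals.
z_upper <- function(alpha) stats::qnorm(1 - alpha)

clip01 <- function(x) pmin(1, pmax(0, x))

clip_theta <- function(x) pmin(1, pmax(-1, x))

# Deterministic seed derivation: a short multiplicative-congruential mix of a
# root seed with stream indices (MINSTD multiplier, modulus 2^31 - 1). All
# intermediates stay below 2^53 so the arithmetic is exact in doubles. Used so
# that simulation sub-streams (pair generation, missingness, analysis RNG) are
# independent of each other and of execution order.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- abs(as.numeric(seed)) %% m
  for (k in c(...)) {
    h <- ((h + abs(as.numeric(k)) + 1) * 48271) %% m
  }
  as.integer(h %% 2147483562) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
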