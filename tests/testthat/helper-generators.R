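# Shared helpers for property-style tests.

# A reproducible batch of random PHFS pairs over a common universe.
random_pair <- function(i, n = 3, max_len = 4) {
  list(A = random_phfs(n, max_len, seed = 2 * i),
       B = random_phfs(n, max_len, seed = 2 * i + 1))
}

uniform_w <- function(n) rep(1 / n, n)

# Literal transcription of the worked information-energy arithmetic for the
# padded pair used throughout the docs: an independent oracle, written as
# explicit sums, never via the package's aligned implementation.
worked_pair_c1_by_hand <- function() {
  (1 / 3) * (0.5 * 0.4 * 0.4 * 0 + 0.7 * 0.3 * 0.4 * 0.3 + 0.8 * 0.3 * 0.5 * 0.7) +
  (1 / 3) * (0.1 * 0.5 * 0.3 * 0.1 + 0.3 * 0.3 * 0.2 * 0.4 + 0.6 * 0.2 * 0.5 * 0.5) +
  (1 / 3) * (0.3 * 0 * 0.3 * 0.2 + 0.3 * 0.3 * 0.8 * 0.1 + 0.2 * 0.7 * 0.7 * 0.7)
}

# absolute-tolerance comparison at published 4-decimal precision
expect_close <- function(object, expected, tol = 5e-5) {
  expect_lt(max(abs(object - expected)), tol)
}
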