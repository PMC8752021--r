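#' Derive a child seed from a master seed and a counter path
#'
#' Deterministic counter-based seed derivation: a master seed plus a path of
#' non-negative integers (e.g. round, evaluation slot, replicate) is folded
#' through a Lehmer-style congruential mix modulo 2^31 - 1, which is exact
#' in double arithmetic. Each distinct path yields an independent-looking
#' seed; the same path always yields the same seed. All randomness in the
#' package flows through seeds derived this way, so a run is reproducible
#' from its master seed alone, and evaluations are independent of execution
#' order.
#'
#' @param seed Master seed (non-negative integer-valued scalar).
#' @param ... Path components (non-negative integer-valued scalars).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, 3, 0) # base evaluation of round 3
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s + as.numeric(k)) %% m
    s <- (48271 * s + 12345) %% m
    s <- (48271 * s + 12345) %% m
  }
  as.integer(s)
}

# Evaluate fn() under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
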