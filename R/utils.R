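## Small shared helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: keeps every derived seed a valid
# 32-bit integer whatever small integer the user supplies.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of drawing at least `k` successes in `n` draws without
#' replacement from a universe of `N` objects of which `K` are successes.
#'
#' @param k Observed overlap.
#' @param K Successes in the universe.
#' @param n Draws.
#' @param N Universe size.
#' @return P(X >= k), exactly 1 when k <= 0.
#' @export
hypergeom_p <- function(k, K, n, N) {
  stopifnot(k <= min(K, n), K <= N, n <= N)
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
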