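#' Derive a child RNG seed from a base seed and a counter path
#'
#' All randomness in the package flows from one user-supplied seed.  Child
#' seeds for independent work units (one subword synthesis, one bootstrap
#' draw, one tree) are derived by mixing the base seed with a path of
#' integer counters through a multiplicative-congruential hash, so the seed
#' of any unit is reproducible independent of the order in which units are
#' generated.
#'
#' @param seed base integer seed.
#' @param ... integer counters identifying the work unit (e.g. class index,
#'   repetition index).
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' split_seed(1, 3, 7)
split_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- as.numeric(seed) %% m
  for (v in c(...)) {
    # Carter-Wegman style mixing; constants from classic LCGs.  All
    # arithmetic stays below 2^53 so doubles are exact.
    h <- (h * 48271 + as.numeric(v) * 16807 + 12345) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
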