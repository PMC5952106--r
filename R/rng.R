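#' Derive a child seed from a root seed
#'
#' Deterministic seed splitting so that every stochastic stage of a pipeline
#' runs on its own reproducible stream. The mixing is a fixed linear
#' congruential step per index, kept below 2^31 so the result is always a
#' valid integer seed.
#'
#' @param seed integer root seed.
#' @param ... integer indices identifying the child stream (e.g. replicate,
#'   stage, imputation number).
#' @return a single integer seed in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' child_seed(1, 3, 7)
child_seed <- function(seed, ...) {
  idx <- as.double(c(...))
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + (k + 1) * 104729 + 12345) %% 2147483647
  }
  as.integer(s) + 1L
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}
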