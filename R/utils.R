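# Internal helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards.  All randomness in the package flows through an
# explicit seed argument and this scope; nothing perturbs the global
# stream.
with_seed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a base seed, kept within
# 32-bit integer range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 2654435761) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
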