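#' Derive a child RNG seed from a master seed and counters
#'
#' Counter-based scheme: each stream is identified by one or more non-negative
#' integers (epoch number, image counter, class index, ...) folded into the
#' master seed with a multiplicative hash. Generation order therefore does not
#' matter: item `i` always receives the same seed regardless of which items
#' were generated before it.
#'
#' @param seed master seed (integer).
#' @param ... further non-negative integer counters.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) {
    stopifnot(is.finite(p))
    acc <- (acc * 69069 + (p %% 2147483629) + 1) %% 2147483629
  }
  as.integer(acc)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483629))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Numerically stable column-wise softmax of a [K, B] logit matrix.
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
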