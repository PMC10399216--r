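# Internal helpers shared across modules.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through explicit seeds via this helper.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Population (n-denominator) standard deviation; pairs with the
# n-denominator RMSE so that RPD = (1 - R2)^(-1/2) holds exactly.
sdN <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# Centered moving average with shrinking windows at the edges.
movingAverage <- function(x, window) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Derive a stream-specific 32-bit sub-seed from a base seed.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
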