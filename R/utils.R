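# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Parabolic (3-point) sub-sample refinement of an extremum at index i.
# Returns the refined time in seconds (1-based index i maps to (i-1)/fs).
# Falls back to the grid time at array edges or degenerate curvature.
refine_time <- function(x, i, fs) {
  n <- length(x)
  if (i <= 1L || i >= n) return((i - 1) / fs)
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) {
    return((i - 1) / fs)
  }
  d <- 0.5 * (x[i - 1L] - x[i + 1L]) / denom
  d <- max(min(d, 0.5), -0.5)
  (i - 1 + d) / fs
}

# Indices of strict interior local maxima / minima.
local_maxima <- function(x) which(diff(sign(diff(x))) == -2) + 1L
local_minima <- function(x) which(diff(sign(diff(x))) == 2) + 1L

# Centered moving average, edges padded by zero (callers discard the record
# margins anyway).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  out <- stats::filter(x, rep(1 / width, width), sides = 2)
  out[is.na(out)] <- 0
  as.numeric(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Prune an alternating local-extrema sequence by prominence: repeatedly
# cancel the adjacent pair with the smallest swing until every remaining
# swing is at least tol (rainflow-style simplification). `idx` are indices
# into the signal `x`, in time order.
prune_extrema <- function(x, idx, tol) {
  idx <- idx[order(idx)]
  while (length(idx) >= 2L) {
    sw <- abs(diff(x[idx]))
    k <- which.min(sw)
    if (sw[k] >= tol) break
    idx <- idx[-c(k, k + 1L)]
  }
  idx
}
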