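# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

# Start/end indices of runs of TRUE in a logical vector.
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Sample indices of a half-open time window [from, to) on a uniform grid.
# O(1): indices are computed from the grid origin and step, not by scanning.
window_idx <- function(time_s, from, to) {
  n <- length(time_s)
  t0 <- time_s[1]
  dt <- (time_s[n] - t0) / (n - 1)
  i0 <- max(1L, as.integer(ceiling((from - t0) / dt - 1e-6)) + 1L)
  i1 <- min(n, as.integer(ceiling((to - t0) / dt - 1e-6)))
  if (i0 > i1) integer(0) else i0:i1
}

# 32-bit FNV-1a hash of a character scalar, for run manifests.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n")) %% 256
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
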