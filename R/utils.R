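# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# 0-based half-open interval overlap (vectorized on the first pair)
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & end1 > start2
}

interval_midpoint <- function(start, end) {
  floor((start + end) / 2)
}

# indices (1-based) of bins whose half-open interval intersects [start, end)
bins_overlapping <- function(start, end, bin_size, n_bins) {
  first <- max(0L, as.integer(floor(start / bin_size)))
  last <- min(n_bins - 1L, as.integer(ceiling(end / bin_size)) - 1L)
  if (last < first) return(integer(0))
  seq.int(first, last) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
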