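# Peak-finding primitives shared by the smartphone (norm peaks) and mocap
# (COM z peaks, foot z minima) paths. Kept minimal and deterministic.

# Indices of interior local maxima. A plateau is represented by its first
# sample (strictly greater than the left neighbour, >= the right one).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  i[v[i] > v[i - 1L] & v[i] >= v[i + 1L]]
}

# Greedy height-priority thinning: accept peaks tallest-first (ties broken by
# earlier time), rejecting any candidate closer than `min_dist` to an
# already-accepted peak. Returns accepted indices in time order.
thin_peaks <- function(times, heights, idx, min_dist) {
  if (!length(idx)) return(integer(0))
  ord <- idx[order(-heights[idx], times[idx])]
  kept_t <- numeric(0)
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept_t) || min(abs(times[j] - kept_t)) >= min_dist) {
      kept <- c(kept, j)
      kept_t <- c(kept_t, times[j])
    }
  }
  kept[order(times[kept])]
}

# Topographic prominence of each peak index: height above the higher of the
# two saddle minima separating it from the nearest taller terrain (or the
# record edge), as in standard peak analysis.
peak_prominence <- function(v, idx) {
  vapply(idx, function(p) {
    h <- v[p]
    # left side
    i <- p
    left_min <- h
    while (i > 1L) {
      i <- i - 1L
      if (v[i] > h) break
      if (v[i] < left_min) left_min <- v[i]
    }
    # right side
    i <- p
    right_min <- h
    n <- length(v)
    while (i < n) {
      i <- i + 1L
      if (v[i] > h) break
      if (v[i] < right_min) right_min <- v[i]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}
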