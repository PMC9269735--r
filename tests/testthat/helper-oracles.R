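# Independent oracles and small constructors used across the suite.

# Exhaustive step-detection oracle: enumerate interior local maxima above
# the mean + k*SD threshold, then keep peaks in descending height order
# (ties: earlier time first), dropping any candidate within min_dist of an
# already-kept peak. O(n^2); independent of the package implementation.
oracle_detect <- function(time, values, k_sd, min_dist) {
  n <- length(values)
  thr <- mean(values) + k_sd * sd(values)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    if (values[i] > values[i - 1L] && values[i] >= values[i + 1L] &&
        values[i] >= thr) {
      cand <- c(cand, i)
    }
  }
  kept <- integer(0)
  while (length(cand)) {
    h <- values[cand]
    best <- cand[which(h == max(h))]
    best <- best[which.min(time[best])]
    kept <- c(kept, best)
    cand <- cand[abs(time[cand] - time[best]) >= min_dist]
  }
  sort(time[kept])
}

# Straight-line lane constructor for unit tests (bypasses split_lanes).
make_lane <- function(time, pelvis, lfoot = NULL, rfoot = NULL) {
  if (is.null(lfoot)) lfoot <- pelvis
  if (is.null(rfoot)) rfoot <- pelvis
  structure(
    list(time = time, pelvis = pelvis, left_foot = lfoot,
         right_foot = rfoot,
         direction = sign(pelvis[nrow(pelvis), 1] - pelvis[1, 1]),
         rotation_applied = 0),
    class = "lane")
}

# Random 3-D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
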