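#' Split a position recording into walking lanes
#'
#' Walking tasks traverse a walkway back and forth; turns occur at the most
#' anterior and most posterior pelvis positions along x. Turning points are
#' located as sign changes of the smoothed forward velocity; runs with an
#' x-extent below `min_extent` are treated as turn jitter and dropped. Each
#' lane is then clipped by `exclusion_m` metres from both of its x-extrema,
#' removing acceleration/deceleration around the turns. When no turning
#' point is found the whole recording is returned as a single lane (with
#' boundary exclusion applied).
#'
#' @param rec A [position_recording()].
#' @param exclusion_m Metres excluded from each lane end (x-direction).
#' @param min_extent Minimum x-extent (m) for a run to count as a lane.
#' @param smooth_s Moving-average window (s) used to smooth pelvis x before
#'   locating turns.
#' @return A list of `lane` objects, ordered in time. Each lane carries
#'   `time`, `pelvis`, `left_foot`, `right_foot`, `direction` (+1/-1 along
#'   x) and `rotation_applied` (radians).
#' @export
split_lanes <- function(rec, exclusion_m = 1, min_extent = 2, smooth_s = 0.5) {
  stopifnot(inherits(rec, "position_recording"))
  x <- rec$pelvis[, 1]
  n <- length(x)
  w <- max(1L, round(smooth_s * rec$rate))
  if (w %% 2L == 0L) w <- w + 1L
  xs <- if (n > w) {
    sm <- stats::filter(x, rep(1 / w, w), sides = 2)
    sm[is.na(sm)] <- x[is.na(sm)]
    as.numeric(sm)
  } else x

  d <- sign(diff(xs))
  # carry direction through flat (turn) stretches
  for (i in seq_along(d)) if (d[i] == 0 && i > 1L) d[i] <- d[i - 1L]
  if (d[1] == 0) d[1] <- d[which(d != 0)[1]]
  r <- rle(d)
  ends <- cumsum(r$lengths) + 1L
  starts <- c(1L, utils::head(ends, -1L))
  extents <- abs(xs[ends] - xs[starts])
  big <- which(extents >= min_extent)

  runs <- if (length(big)) {
    lapply(big, function(k) c(starts[k], ends[k]))
  } else {
    list(c(1L, n))  # no turning point: single-lane fallback
  }

  lanes <- lapply(runs, function(se) {
    idx <- se[1]:se[2]
    lx <- x[idx]
    lo <- min(lx) + exclusion_m
    hi <- max(lx) - exclusion_m
    inside <- which(lx >= lo & lx <= hi)
    if (length(inside) < 2L) return(NULL)
    idx <- idx[min(inside):max(inside)]
    new_lane(rec, idx)
  })
  lanes[!vapply(lanes, is.null, logical(1))]
}

new_lane <- function(rec, idx) {
  pel <- rec$pelvis[idx, , drop = FALSE]
  structure(
    list(time = rec$time[idx], pelvis = pel,
         left_foot = rec$left_foot[idx, , drop = FALSE],
         right_foot = rec$right_foot[idx, , drop = FALSE],
         direction = sign(pel[nrow(pel), 1] - pel[1, 1]),
         rotation_applied = 0),
    class = "lane")
}

#' @export
print.lane <- function(x, ...) {
  cat(sprintf("<lane> %d samples, %.1f s, direction %+d, rotation %.2f deg\n",
              length(x$time), diff(range(x$time)), x$direction,
              x$rotation_applied * 180 / pi))
  invisible(x)
}

#' Drift-correct a lane by rotation in the moving plane
#'
#' IMU heading drift makes a lane's apparent travel direction rotate away
#' from the x-axis. The lane is corrected by rotating all three point
#' streams in the x-y plane by the angle that aligns the pelvis
#' net-displacement vector (first to last sample) with +x; z is untouched
#' and the applied angle is recorded. Lanes walked in the -x direction are
#' thereby also brought to forward (+x) progression.
#'
#' @param lane A `lane` from [split_lanes()].
#' @return The aligned lane; `rotation_applied` accumulates the rotation in
#'   radians.
#' @export
align_lane <- function(lane) {
  stopifnot(inherits(lane, "lane"))
  n <- nrow(lane$pelvis)
  if (n < 2L) stop("lane needs at least 2 samples")
  net <- lane$pelvis[n, 1:2] - lane$pelvis[1, 1:2]
  if (sqrt(sum(net^2)) < 1e-12) stop("zero net displacement: cannot align lane")
  theta <- atan2(net[2], net[1])
  R <- matrix(c(cos(-theta), -sin(-theta), sin(-theta), cos(-theta)),
              2L, 2L, byrow = TRUE)
  rot <- function(m) { m[, 1:2] <- m[, 1:2] %*% t(R); m }
  lane$pelvis <- rot(lane$pelvis)
  lane$left_foot <- rot(lane$left_foot)
  lane$right_foot <- rot(lane$right_foot)
  lane$rotation_applied <- lane$rotation_applied - theta
  lane$direction <- 1
  lane
}

#' Detect step cycles from vertical COM peaks
#'
#' The centre of mass moves up and down cyclically during walking; each
#' local maximum of pelvis z marks a step cycle. Peaks must reach the given
#' topographic prominence and be at least `min_dist` seconds apart (taller
#' peak wins).
#'
#' @param lane A `lane`.
#' @param min_prominence Minimum peak prominence in metres.
#' @param min_dist Minimum peak spacing in seconds.
#' @return A `step_events` vector of peak times (possibly empty).
#' @export
detect_com_steps <- function(lane, min_prominence = 0.005, min_dist = 0.3) {
  stopifnot(inherits(lane, "lane"))
  if (diff(range(lane$time)) < 2 * min_dist) {
    stop("lane shorter than twice the minimum peak distance")
  }
  z <- lane$pelvis[, 3]
  idx <- local_maxima(z)
  if (length(idx)) {
    prom <- peak_prominence(z, idx)
    idx <- idx[prom >= min_prominence]
  }
  kept <- thin_peaks(lane$time, z, idx, min_dist)
  structure(lane$time[kept], class = "step_events",
            k_sd = NA_real_, min_dist = min_dist)
}

#' Per-lane gait velocity
#'
#' Distance between the first and last pelvis position in the moving (x-y)
#' plane divided by the elapsed time. Invariant under the drift-correction
#' rotation (an isometry).
#'
#' @param lane A `lane` (aligned or not).
#' @return Velocity in m/s.
#' @export
lane_velocity <- function(lane) {
  stopifnot(inherits(lane, "lane"))
  n <- nrow(lane$pelvis)
  d <- sqrt(sum((lane$pelvis[n, 1:2] - lane$pelvis[1, 1:2])^2))
  dt <- lane$time[n] - lane$time[1]
  d / dt
}

#' Step width from mid-stance foot minima
#'
#' Mid-stance of each foot is marked by the minima of its vertical (z)
#' position; the medial-lateral (y) positions of the left and right foot at
#' paired mid-stance frames give the step width `|y_left - y_right|`.
#' Left and right minima are paired by nearest time (greedy, each minimum
#' used once); unpaired minima are dropped.
#'
#' @param lane An aligned `lane` with both foot streams.
#' @param min_prominence Minimum depth (m) of a foot-z minimum.
#' @param min_dist Minimum spacing (s) between minima of the same foot.
#' @return Mean step width for the lane in metres (`NA` if no pair found),
#'   with attribute `widths` holding the per-pair values.
#' @export
step_width <- function(lane, min_prominence = 0.005, min_dist = 0.3) {
  stopifnot(inherits(lane, "lane"))
  foot_minima <- function(foot) {
    z <- -foot[, 3]
    idx <- local_maxima(z)
    if (length(idx)) {
      prom <- peak_prominence(z, idx)
      idx <- idx[prom >= min_prominence]
    }
    thin_peaks(lane$time, z, idx, min_dist)
  }
  li <- foot_minima(lane$left_foot)
  ri <- foot_minima(lane$right_foot)
  if (!length(li) || !length(ri)) {
    return(structure(NA_real_, widths = numeric(0)))
  }
  # greedy nearest-time pairing, each minimum used at most once
  pairs <- expand.grid(l = seq_along(li), r = seq_along(ri))
  pairs$dt <- abs(lane$time[li[pairs$l]] - lane$time[ri[pairs$r]])
  pairs <- pairs[order(pairs$dt), ]
  used_l <- logical(length(li)); used_r <- logical(length(ri))
  widths <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    pl <- pairs$l[k]; pr <- pairs$r[k]
    if (!used_l[pl] && !used_r[pr]) {
      used_l[pl] <- TRUE; used_r[pr] <- TRUE
      widths <- c(widths,
                  abs(lane$left_foot[li[pl], 2] - lane$right_foot[ri[pr], 2]))
    }
  }
  structure(mean(widths), widths = widths)
}

#' Mocap gait features for a full recording
#'
#' Splits the recording into lanes, drift-corrects each by rotation,
#' detects COM step cycles per lane, and aggregates: stride time (MSI) and
#' cadence from inter-step times pooled within lanes, velocity and step
#' width as unweighted means over lanes.
#'
#' @param rec A [position_recording()].
#' @param task Gait task; tandem uses a wider COM peak spacing.
#' @param exclusion_m Lane-end exclusion in metres.
#' @param min_prominence COM / foot peak prominence in metres.
#' @param min_dist COM peak spacing in seconds (`NULL`: 0.3, or 0.45 for
#'   tandem).
#' @return A list with `stride_time`, `cadence`, `velocity`, `step_width`,
#'   `n_steps`, `n_lanes`, and `lanes` (the aligned lanes).
#' @export
mocap_gait_features <- function(rec, task = "normal", exclusion_m = 1,
                                min_prominence = 0.005, min_dist = NULL) {
  if (is.null(min_dist)) min_dist <- if (task == "tandem") 0.45 else 0.3
  lanes <- split_lanes(rec, exclusion_m = exclusion_m)
  if (!length(lanes)) stop("no usable lanes found")
  lanes <- lapply(lanes, align_lane)
  steps <- lapply(lanes, detect_com_steps, min_prominence = min_prominence,
                  min_dist = min_dist)
  sm <- pooled_stride_metrics(steps)
  vels <- vapply(lanes, lane_velocity, numeric(1))
  widths <- vapply(lanes, function(l) {
    as.numeric(step_width(l, min_prominence = min_prominence,
                          min_dist = min_dist))
  }, numeric(1))
  list(stride_time = sm$msi, cadence = sm$cadence,
       velocity = mean(vels),
       step_width = if (all(is.na(widths))) NA_real_
                    else mean(widths, na.rm = TRUE),
       n_steps = sm$n_steps, n_lanes = length(lanes), lanes = lanes)
}
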