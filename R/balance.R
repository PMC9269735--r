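#' Path length of a planar COM trace
#'
#' Sum of Euclidean distances between all successive points in the moving
#' (x-y) plane.
#'
#' @param xy Numeric matrix (n x 2), millimetres.
#' @return Path length in mm.
#' @export
com_path_length <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Sway velocity
#'
#' Millimetres the COM travelled per second: path length over duration.
#'
#' @param path_length Path length in mm.
#' @param duration Task duration in seconds, positive.
#' @return Sway velocity in mm/s.
#' @export
sway_velocity <- function(path_length, duration) {
  if (duration <= 0) stop("`duration` must be positive")
  path_length / duration
}

#' Sway ellipse area (mocap convention)
#'
#' Anteroposterior sway is half the x-range, mediolateral sway half the
#' y-range; the ellipse area is `pi * AP * ML`. With half-ranges as
#' semi-axes the ellipse encloses 100% of the points along each axis.
#'
#' @param xy Numeric matrix (n x 2) of COM positions in mm
#'   (x = anterior-posterior, y = medial-lateral).
#' @return Area in mm^2, with attributes `ap_sway` and `ml_sway` (mm).
#' @export
ellipse_area_mocap <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) stop("need at least 2 samples")
  ap <- diff(range(xy[, 1])) / 2
  ml <- diff(range(xy[, 2])) / 2
  structure(pi * ap * ml, ap_sway = ap, ml_sway = ml)
}

#' Displacement from stance-task acceleration
#'
#' Double integration with interleaved band-pass filtering, per axis:
#' filter the acceleration, integrate to velocity, filter, integrate to
#' displacement, filter again. The repeated filtering removes residual
#' gravitational and reintroduced low-frequency content. Output is in
#' millimetres.
#'
#' @param rec An [accel_recording()] of a stance task, trimmed.
#' @param config A [pipeline_config()] for filter settings.
#' @param edge_guard Seconds discarded at each end after integration
#'   (filter/integration transients).
#' @return A list with `time` and `disp` (n x 3 matrix, mm, mean-centred);
#'   attribute `unstable = TRUE` when the recording is shorter than 5 s.
#' @export
displacement_from_accel <- function(rec, config = pipeline_config(),
                                    edge_guard = 1) {
  stopifnot(inherits(rec, "accel_recording"))
  if (rec$rate > config$resample_rate * (1 + 1e-9)) {
    rec <- resample_accel(rec, config$resample_rate)
  }
  unstable <- diff(range(rec$time)) < 5
  bp <- function(m) bandpass(m, rec$rate, low = config$band_low,
                             high = config$band_high,
                             order = config$filter_order,
                             zero_phase = config$zero_phase)
  disp <- bp(integrate_series(bp(integrate_series(bp(rec$acc), rec$time)),
                              rec$time)) * 1000
  keep <- rec$time >= rec$time[1] + edge_guard &
    rec$time <= rec$time[length(rec$time)] - edge_guard
  if (sum(keep) < 2L) keep <- rep(TRUE, length(rec$time))
  disp <- disp[keep, , drop = FALSE]
  disp <- sweep(disp, 2L, colMeans(disp))
  out <- list(time = rec$time[keep], disp = disp)
  if (unstable) attr(out, "unstable") <- TRUE
  out
}

#' 95% PCA sway ellipsoid volume
#'
#' Principal component analysis of the 3-D displacement cloud gives the
#' main sway directions; the ellipsoid encompassing the 95% confidence
#' region across the three principal components has semi-axes
#' `sqrt(qchisq(0.95, 3)) * sigma_i` (about 2.7955 per-component SDs, a
#' joint rather than per-axis 95% statement) and volume
#' `(4/3) * pi * prod(semi-axes)`.
#'
#' @param disp Numeric matrix (n x 3) of displacements in mm; n >= 10.
#' @param conf Confidence level for the chi-square quantile.
#' @return Object of class `sway_ellipsoid`: list with `volume` (mm^3),
#'   `semi_axes`, `sd` (per-component SDs), `scaling` (the chi-square
#'   scaling constant), `rotation` (principal axes) and `degenerate`.
#' @export
ellipsoid_volume_pca <- function(disp, conf = 0.95) {
  disp <- as.matrix(disp)
  if (ncol(disp) != 3L) stop("`disp` must have 3 columns")
  if (nrow(disp) < 10L) stop("need at least 10 samples")
  centred <- sweep(disp, 2L, colMeans(disp))
  ev <- eigen(stats::cov(centred), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  scaling <- sqrt(stats::qchisq(conf, df = 3))
  degenerate <- any(lambda <= 1e-12 * max(lambda, 1e-300))
  sd_pc <- sqrt(lambda)
  semi <- scaling * sd_pc
  vol <- if (degenerate) 0 else (4 / 3) * pi * prod(semi)
  structure(
    list(volume = vol, semi_axes = semi, sd = sd_pc, scaling = scaling,
         rotation = ev$vectors, degenerate = degenerate),
    class = "sway_ellipsoid")
}

#' @export
print.sway_ellipsoid <- function(x, ...) {
  cat(sprintf("<sway_ellipsoid> volume %.2f mm^3 (scaling %.4f%s)\n",
              x$volume, x$scaling,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Smartphone sway velocity from a displacement trace
#'
#' Point-by-point 3-D displacement path length divided by duration.
#'
#' @param disp Numeric matrix (n x 3), mm.
#' @param time Timestamps in seconds.
#' @return Sway velocity in mm/s.
#' @export
smartphone_sway_velocity <- function(disp, time) {
  disp <- as.matrix(disp)
  if (nrow(disp) < 2L) stop("need at least 2 samples")
  path <- sum(sqrt(rowSums(diff(disp)^2)))
  path / diff(range(time))
}

#' Smartphone balance features for a stance recording
#'
#' Transforms acceleration to displacement (band-pass, double integration),
#' then computes the PCA 95% ellipsoid volume and the point-by-point sway
#' velocity. The phone's axes are not fixed in space, so sway is summarised
#' in 3-D via PCA rather than as a planar ellipse.
#'
#' @param rec An [accel_recording()] of a stance task.
#' @param config A [pipeline_config()].
#' @return A list with `sway_volume` (mm^3), `sway_velocity` (mm/s),
#'   `path_length` (mm), `duration` (s), `scaling`, `degenerate`,
#'   `unstable`.
#' @export
smartphone_balance_features <- function(rec, config = pipeline_config()) {
  d <- displacement_from_accel(rec, config = config)
  ell <- ellipsoid_volume_pca(d$disp, conf = config$ellipsoid_conf)
  duration <- diff(range(d$time))
  path <- sum(sqrt(rowSums(diff(d$disp)^2)))
  list(sway_volume = ell$volume,
       sway_velocity = path / duration,
       path_length = path, duration = duration,
       scaling = ell$scaling, degenerate = ell$degenerate,
       unstable = isTRUE(attr(d, "unstable")))
}

#' Mocap balance features for a stance recording
#'
#' Uses the pelvis (COM) positions: planar (x-y) path length, sway velocity
#' and the half-range ellipse area, in millimetres.
#'
#' @param rec A [position_recording()] of a stance task.
#' @return A list with `sway_area` (mm^2), `sway_velocity` (mm/s),
#'   `path_length` (mm), `ap_sway`, `ml_sway` (mm), `duration` (s).
#' @export
mocap_balance_features <- function(rec) {
  stopifnot(inherits(rec, "position_recording"))
  xy <- rec$pelvis[, 1:2] * 1000
  duration <- diff(range(rec$time))
  path <- com_path_length(xy)
  area <- ellipse_area_mocap(xy)
  list(sway_area = as.numeric(area),
       sway_velocity = sway_velocity(path, duration),
       path_length = path,
       ap_sway = attr(area, "ap_sway"), ml_sway = attr(area, "ml_sway"),
       duration = duration)
}
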