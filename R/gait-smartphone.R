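#' Detector parameters for norm-peak step detection
#'
#' Study-calibrated defaults: normal and backward gait use a minimum peak
#' height of 2.3 SD above the mean of the filtered norm and a minimum peak
#' distance of 0.38 s; tandem gait uses 2.7 SD and 0.42 s.
#'
#' @param task One of `"normal"`, `"backward"`, `"tandem"`.
#' @return A list with `k_sd` (SD units) and `min_dist` (seconds).
#' @export
detector_defaults <- function(task = c("normal", "backward", "tandem")) {
  task <- match.arg(task)
  if (task == "tandem") list(k_sd = 2.7, min_dist = 0.42)
  else list(k_sd = 2.3, min_dist = 0.38)
}

#' Detect step peaks on a filtered acceleration norm
#'
#' Finds all interior local maxima of `values` at or above
#' `mean(values) + k_sd * sd(values)`, then greedily thins them so that
#' consecutive peaks are at least `min_dist` seconds apart, the taller peak
#' winning (ties keep the earlier peak). The threshold is expressed in SD
#' units relative to the mean signal, making detection invariant to
#' amplitude scaling.
#'
#' @param time Numeric timestamps (seconds), uniform rate.
#' @param values Band-pass-filtered acceleration norm.
#' @param k_sd Minimum peak height in SD units above the mean.
#' @param min_dist Minimum peak distance in seconds.
#' @return Object of class `step_events`: numeric vector of peak times with
#'   attributes `k_sd` and `min_dist`.
#' @export
detect_steps <- function(time, values, k_sd = 2.3, min_dist = 0.38) {
  if (k_sd <= 0 || min_dist <= 0) stop("`k_sd` and `min_dist` must be positive")
  if (length(time) != length(values)) stop("`time`/`values` lengths differ")
  if (diff(range(time)) < 2 * min_dist) {
    stop("series shorter than twice the minimum peak distance")
  }
  thr <- mean(values) + k_sd * stats::sd(values)
  cand <- local_maxima(values)
  cand <- cand[values[cand] >= thr]
  kept <- thin_peaks(time, values, cand, min_dist)
  structure(time[kept], class = "step_events", k_sd = k_sd,
            min_dist = min_dist)
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events> %d peaks (k_sd=%.2f, min_dist=%.2f s)\n",
              length(x), attr(x, "k_sd"), attr(x, "min_dist")))
  invisible(x)
}

#' Stride metrics from step-peak times
#'
#' Inter-step times are successive differences of the peak times; a stride
#' is two consecutive steps, so stride times are sums of adjacent inter-step
#' pairs. The mean stride interval (MSI) is the mean stride time; cadence is
#' the inverse of the mean inter-step time.
#'
#' @param peak_times Numeric vector of strictly increasing step-peak times
#'   (seconds), or a `step_events` object; at least 3 peaks.
#' @return A list with `inter_step_times`, `stride_times`, `msi` (s),
#'   `cadence` (steps/s) and `n_steps`.
#' @export
stride_metrics <- function(peak_times) {
  t <- as.numeric(peak_times)
  if (length(t) < 3L) stop("insufficient data: need at least 3 step peaks")
  inter <- diff(t)
  stride <- inter[-length(inter)] + inter[-1L]
  list(inter_step_times = inter, stride_times = stride,
       msi = mean(stride), cadence = 1 / mean(inter), n_steps = length(t))
}

# Pool stride metrics over disjoint task windows (e.g. lanes): inter-step
# and stride times are computed within each window only, never across turns.
pooled_stride_metrics <- function(peak_times_list) {
  ok <- peak_times_list[vapply(peak_times_list, length, 1L) >= 3L]
  if (!length(ok)) stop("insufficient data: no window has >= 3 step peaks")
  inter <- unlist(lapply(ok, function(t) diff(as.numeric(t))))
  stride <- unlist(lapply(ok, function(t) {
    d <- diff(as.numeric(t)); d[-length(d)] + d[-1L]
  }))
  list(inter_step_times = inter, stride_times = stride,
       msi = mean(stride), cadence = 1 / mean(inter),
       n_steps = sum(vapply(ok, length, 1L)))
}

#' Smartphone gait features from an acceleration recording
#'
#' Full smartphone gait path: resample to the common analysis rate,
#' band-pass filter each axis, take the Euclidean norm, detect step peaks
#' with the task defaults (or explicit parameters), and compute stride
#' time (MSI), cadence and double-integration velocity. When `windows` (a
#' matrix of `[start, end)` rows, e.g. ground-truth lane windows with turns
#' removed) is given, detection and stride pooling are done per window.
#'
#' @param rec An [accel_recording()].
#' @param task Gait task, selects detector defaults.
#' @param k_sd,min_dist Detector overrides; `NULL` uses the task defaults.
#' @param windows Optional n x 2 matrix of task windows in seconds.
#' @param edge_guard Seconds excluded at each end of the recording (or of
#'   each window) from peak statistics, guarding against filter transients.
#' @param config A [pipeline_config()] supplying filter settings.
#' @param compute_velocity Set `FALSE` to skip the double-integration
#'   velocity (cheaper when only timing features are needed).
#' @return A list with `stride_time`, `cadence`, `velocity`, `n_steps`,
#'   `step_times`.
#' @export
smartphone_gait_features <- function(rec, task = "normal", k_sd = NULL,
                                     min_dist = NULL, windows = NULL,
                                     edge_guard = 1,
                                     config = pipeline_config(),
                                     compute_velocity = TRUE) {
  defs <- detector_defaults(task)
  if (is.null(k_sd)) k_sd <- defs$k_sd
  if (is.null(min_dist)) min_dist <- defs$min_dist
  fn <- filtered_norm(rec, low = config$band_low, high = config$band_high,
                      order = config$filter_order,
                      zero_phase = config$zero_phase,
                      resample_rate = config$resample_rate)
  if (is.null(windows)) {
    windows <- matrix(c(min(fn$time) + edge_guard,
                        max(fn$time) - edge_guard + 1e-9), nrow = 1L)
  }
  peaks <- detect_windowed_steps(fn, windows, k_sd, min_dist)
  sm <- pooled_stride_metrics(peaks)
  vel <- if (compute_velocity) {
    as.numeric(estimate_velocity(rec, config = config))
  } else NA_real_
  list(stride_time = sm$msi, cadence = sm$cadence,
       velocity = vel, n_steps = sm$n_steps,
       step_times = sort(unlist(peaks)))
}

# Detect steps separately inside each window of a filtered norm. Threshold
# statistics (mean, SD) are computed over the union of windows, i.e. the
# task samples with turns excluded.
detect_windowed_steps <- function(fn, windows, k_sd, min_dist) {
  windows <- matrix(as.numeric(windows), ncol = 2L)
  in_task <- rep(FALSE, length(fn$time))
  for (i in seq_len(nrow(windows))) {
    in_task <- in_task | (fn$time >= windows[i, 1] & fn$time < windows[i, 2])
  }
  if (!any(in_task)) stop("no samples fall inside the task windows")
  thr <- mean(fn$norm[in_task]) + k_sd * stats::sd(fn$norm[in_task])
  lapply(seq_len(nrow(windows)), function(i) {
    keep <- fn$time >= windows[i, 1] & fn$time < windows[i, 2]
    t <- fn$time[keep]; v <- fn$norm[keep]
    if (length(v) < 3L) return(numeric(0))
    cand <- local_maxima(v)
    cand <- cand[v[cand] >= thr]
    t[thin_peaks(t, v, cand, min_dist)]
  })
}

#' Grid specification for detector calibration
#'
#' The study grid: peak height 1.5 SD in steps of 0.1 to 3.0 SD, peak
#' distance 0.2 s in steps of 0.02 to 0.44 s.
#'
#' @param k_sd Vector of peak-height thresholds in SD units.
#' @param min_dist Vector of minimum peak distances in seconds.
#' @return A list with the two axes.
#' @export
grid_spec <- function(k_sd = seq(1.5, 3.0, by = 0.1),
                      min_dist = seq(0.20, 0.44, by = 0.02)) {
  stopifnot(all(k_sd > 0), all(min_dist > 0))
  list(k_sd = k_sd, min_dist = min_dist)
}

#' Grid-search calibration of the step detector
#'
#' For every `(k_sd, min_dist)` cell, detects steps on each calibration
#' recording, computes the per-recording mean stride interval (MSI), and
#' correlates detected MSIs against ground-truth MSIs (Pearson) across
#' recordings. The optimum cell attains the maximal correlation; ties go to
#' the smallest `k_sd`, then the smallest `min_dist`. Recordings where a
#' cell yields fewer than 3 peaks are treated as missing for that cell
#' (pairwise-complete correlation, flagged when fewer than 3 remain).
#'
#' @param recordings List of [accel_recording()] objects.
#' @param truth_msi Numeric vector of ground-truth MSIs, one per recording.
#' @param grid A [grid_spec()].
#' @param windows_list Optional list (one element per recording) of n x 2
#'   task-window matrices (turns removed); `NULL` uses each full recording.
#' @param edge_guard Seconds trimmed from each recording end when no
#'   windows are given.
#' @param config A [pipeline_config()] for filter settings.
#' @return Object of class `grid_result`: list with `surface` (data frame
#'   `k_sd, min_dist, r, n, flagged`), `optimum`, `n_recordings`.
#' @export
calibrate_grid <- function(recordings, truth_msi, grid = grid_spec(),
                           windows_list = NULL, edge_guard = 1,
                           config = pipeline_config()) {
  nrec <- length(recordings)
  if (nrec < 3L) stop("need at least 3 calibration recordings")
  if (length(truth_msi) != nrec) stop("`truth_msi` length must match recordings")

  # Precompute, per recording and window: candidate local maxima with their
  # times/heights, plus in-task mean and SD of the filtered norm. Each grid
  # cell then only thresholds and thins.
  prep <- lapply(seq_len(nrec), function(i) {
    fn <- filtered_norm(recordings[[i]], low = config$band_low,
                        high = config$band_high, order = config$filter_order,
                        zero_phase = config$zero_phase,
                        resample_rate = config$resample_rate)
    win <- if (is.null(windows_list)) {
      matrix(c(min(fn$time) + edge_guard, max(fn$time) - edge_guard + 1e-9),
             nrow = 1L)
    } else matrix(as.numeric(windows_list[[i]]), ncol = 2L)
    in_task <- rep(FALSE, length(fn$time))
    for (k in seq_len(nrow(win))) {
      in_task <- in_task | (fn$time >= win[k, 1] & fn$time < win[k, 2])
    }
    wins <- lapply(seq_len(nrow(win)), function(k) {
      keep <- fn$time >= win[k, 1] & fn$time < win[k, 2]
      t <- fn$time[keep]; v <- fn$norm[keep]
      idx <- local_maxima(v)
      list(t = t[idx], v = v[idx])
    })
    list(mu = mean(fn$norm[in_task]), sdev = stats::sd(fn$norm[in_task]),
         wins = wins)
  })

  cell_msi <- function(k_sd, min_dist) {
    vapply(prep, function(p) {
      thr <- p$mu + k_sd * p$sdev
      peaks <- lapply(p$wins, function(w) {
        sel <- which(w$v >= thr)
        w$t[thin_peaks(w$t, w$v, sel, min_dist)]
      })
      ok <- peaks[vapply(peaks, length, 1L) >= 3L]
      if (!length(ok)) return(NA_real_)
      pooled_stride_metrics(ok)$msi
    }, numeric(1))
  }

  surface <- expand.grid(k_sd = grid$k_sd, min_dist = grid$min_dist,
                         KEEP.OUT.ATTRS = FALSE)
  surface$r <- NA_real_
  surface$n <- 0L
  for (j in seq_len(nrow(surface))) {
    det <- cell_msi(surface$k_sd[j], surface$min_dist[j])
    ok <- stats::complete.cases(det, truth_msi)
    surface$n[j] <- sum(ok)
    if (sum(ok) >= 2L && stats::sd(det[ok]) > 0 && stats::sd(truth_msi[ok]) > 0) {
      surface$r[j] <- stats::cor(det[ok], truth_msi[ok])
    }
  }
  surface$flagged <- surface$n < 3L

  usable <- which(!is.na(surface$r) & !surface$flagged)
  if (!length(usable)) usable <- which(!is.na(surface$r))
  if (!length(usable)) stop("no grid cell produced a defined correlation")
  best_r <- max(surface$r[usable])
  cand <- usable[surface$r[usable] == best_r]
  cand <- cand[order(surface$k_sd[cand], surface$min_dist[cand])]
  opt <- cand[1L]

  structure(
    list(surface = surface,
         optimum = list(k_sd = surface$k_sd[opt],
                        min_dist = surface$min_dist[opt],
                        r = surface$r[opt], n = surface$n[opt]),
         n_recordings = nrec),
    class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(
    "<grid_result> %d cells, %d recordings; optimum k_sd=%.1f SD, min_dist=%.2f s (r=%.4f, n=%d)\n",
    nrow(x$surface), x$n_recordings, x$optimum$k_sd, x$optimum$min_dist,
    x$optimum$r, x$optimum$n))
  invisible(x)
}

#' Mean gait velocity by step-wise double integration
#'
#' Band-pass filters the acceleration, integrates to velocity, re-applies
#' the band-pass (removing residual gravitational and reintroduced
#' low-frequency content), integrates to displacement and filters once
#' more. Distance covered is the summed point-to-point path length of the
#' 3-D displacement over the window; mean velocity is distance divided by
#' the window duration.
#'
#' @param rec An [accel_recording()], trimmed to the task.
#' @param window Optional `c(start, end)` window in seconds.
#' @param config A [pipeline_config()] for filter settings.
#' @return Mean velocity in m/s. Windows shorter than 5 s get attribute
#'   `unstable = TRUE` (integration unreliable).
#' @export
estimate_velocity <- function(rec, window = NULL, config = pipeline_config()) {
  stopifnot(inherits(rec, "accel_recording"))
  if (!is.null(window)) rec <- trim_segment(rec, window[1], window[2])
  if (rec$rate > config$resample_rate * (1 + 1e-9)) {
    rec <- resample_accel(rec, config$resample_rate)
  }
  duration <- diff(range(rec$time))
  unstable <- duration < 5
  bp <- function(m) bandpass(m, rec$rate, low = config$band_low,
                             high = config$band_high,
                             order = config$filter_order,
                             zero_phase = config$zero_phase)
  disp <- bp(integrate_series(bp(integrate_series(bp(rec$acc), rec$time)),
                              rec$time))
  dist <- sum(sqrt(rowSums(diff(disp)^2)))
  out <- dist / duration
  if (unstable) attr(out, "unstable") <- TRUE
  out
}
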