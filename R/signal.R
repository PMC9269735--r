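#' Zero-phase Butterworth band-pass filter
#'
#' Filters a signal (vector, or matrix column-wise) with a Butterworth
#' band-pass. The default band of 0.8-20 Hz retains the locomotor band while
#' removing the gravitational (DC) component and high-frequency sensor
#' noise. The filter is applied forward-backward (`zero_phase = TRUE`) so
#' that peak times are not biased, after reflect-padding each end to limit
#' edge transients.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param rate Sampling rate in Hz.
#' @param low,high Band edges in Hz; requires `0 < low < high < rate/2`.
#' @param order Butterworth order (per band edge).
#' @param zero_phase Apply forward-backward filtering (no phase shift).
#' @param pad_s Reflect-padding length in seconds at each end.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, rate, low = 0.8, high = 20, order = 4,
                     zero_phase = TRUE, pad_s = 1) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= rate / 2) stop("`high` must be below the Nyquist rate ", rate / 2)
  if (is.matrix(x)) {
    return(apply(x, 2L, bandpass, rate = rate, low = low, high = high,
                 order = order, zero_phase = zero_phase, pad_s = pad_s))
  }
  n <- length(x)
  if (n < 4L) stop("signal too short to filter")
  np <- min(max(1L, round(pad_s * rate)), n - 1L)
  padded <- c(rev(x[2L:(np + 1L)]), x, rev(x[(n - np):(n - 1L)]))
  # remove the mean first: the band-pass has zero DC gain, so this changes
  # nothing analytically but kills the start-up transient a large constant
  # (gravity) offset would otherwise leave at the edges
  padded <- padded - mean(padded)
  flt <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  y <- if (zero_phase) signal::filtfilt(flt, padded)
       else as.numeric(signal::filter(flt, padded))
  y[(np + 1L):(np + n)]
}

#' Per-sample Euclidean norm of a tri-axial signal
#'
#' @param acc Numeric matrix (n x 3).
#' @return Numeric vector of per-sample L2 norms (non-negative).
#' @export
euclidean_norm <- function(acc) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop("`acc` must have 3 columns")
  sqrt(rowSums(acc^2))
}

#' Cumulative trapezoidal integration
#'
#' Integrates a uniformly sampled series with the trapezoidal rule, using the
#' first point as the reference: `out[1] == initial`.
#'
#' @param values Numeric vector or matrix (columns integrated independently).
#' @param time Numeric time base in seconds, uniform within `tol`.
#' @param initial Initial value of the integral.
#' @param tol Maximum allowed relative deviation of any time step from the
#'   median step.
#' @return Integrated series, same shape as `values`.
#' @export
integrate_series <- function(values, time, initial = 0, tol = 0.05) {
  dt <- diff(time)
  if (length(dt) < 1L) stop("need at least 2 samples")
  if (any(abs(dt - stats::median(dt)) > tol * stats::median(dt))) {
    stop("time base is not uniform within tolerance")
  }
  out <- pracma::cumtrapz(time, values)
  out <- out + initial
  if (!is.matrix(values)) out <- as.numeric(out)
  out
}

#' Resample a recording to a lower uniform rate
#'
#' Linear interpolation onto a uniform grid at `target_rate`, preserving the
#' start time. Upsampling is refused: recordings captured at device-specific
#' rates (100-252 Hz in practice) are brought down to a common rate so that
#' detector thresholds in seconds map to fixed sample counts.
#'
#' @param rec An [accel_recording()].
#' @param target_rate Target rate in Hz, at most the original rate.
#' @return A resampled [accel_recording()].
#' @export
resample_accel <- function(rec, target_rate) {
  stopifnot(inherits(rec, "accel_recording"))
  if (target_rate > rec$rate * (1 + 1e-9)) {
    stop("upsampling requested: target ", target_rate, " Hz > recording rate ",
         signif(rec$rate, 6), " Hz")
  }
  t0 <- rec$time[1]; t1 <- rec$time[length(rec$time)]
  new_time <- seq(t0, t1, by = 1 / target_rate)
  acc <- vapply(1:3, function(j) {
    stats::approx(rec$time, rec$acc[, j], xout = new_time)$y
  }, numeric(length(new_time)))
  accel_recording(new_time, acc, rate = target_rate, task = rec$task,
                  device = rec$device)
}

#' Trim a recording to a time window
#'
#' Keeps samples with `start <= time < end`; original timestamps are
#' preserved (no re-zeroing). Works on both acceleration and position
#' recordings. Used to cut non-task periods and identified turns.
#'
#' @param rec An [accel_recording()] or [position_recording()].
#' @param start,end Window in seconds, `start < end`.
#' @return A recording of the same class.
#' @export
trim_segment <- function(rec, start, end) {
  if (start >= end) stop("`start` must be < `end`")
  keep <- rec$time >= start & rec$time < end
  if (!any(keep)) stop("trim window [", start, ", ", end, ") contains no samples")
  if (inherits(rec, "accel_recording")) {
    accel_recording(rec$time[keep], rec$acc[keep, , drop = FALSE],
                    rate = rec$rate, task = rec$task, device = rec$device)
  } else if (inherits(rec, "position_recording")) {
    position_recording(rec$time[keep], rec$pelvis[keep, , drop = FALSE],
                       rec$left_foot[keep, , drop = FALSE],
                       rec$right_foot[keep, , drop = FALSE],
                       rate = rec$rate, task = rec$task)
  } else {
    stop("unsupported recording class")
  }
}

#' Band-pass filtered acceleration norm
#'
#' Convenience for the smartphone gait path: filter each axis, then take the
#' per-sample Euclidean norm. Recordings above `resample_rate` are first
#' resampled down.
#'
#' @param rec An [accel_recording()].
#' @param low,high,order,zero_phase Filter settings, see [bandpass()].
#' @param resample_rate Common analysis rate in Hz (`NULL` to skip).
#' @return A list with `time` and `norm`.
#' @export
filtered_norm <- function(rec, low = 0.8, high = 20, order = 4,
                          zero_phase = TRUE, resample_rate = 100) {
  stopifnot(inherits(rec, "accel_recording"))
  if (!is.null(resample_rate) && rec$rate > resample_rate * (1 + 1e-9)) {
    rec <- resample_accel(rec, resample_rate)
  }
  filt <- bandpass(rec$acc, rec$rate, low = low, high = high, order = order,
                   zero_phase = zero_phase)
  list(time = rec$time, norm = euclidean_norm(filt), rate = rec$rate)
}
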