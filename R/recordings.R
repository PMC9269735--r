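#' Tri-axial acceleration recording
#'
#' Container for a timestamped tri-axial acceleration stream from one device
#' and task. Axis convention: `ax` = anterior-posterior, `ay` =
#' medial-lateral, `az` = vertical (carries gravity in raw recordings).
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param acc Numeric matrix (n x 3) of accelerations in m/s^2.
#' @param rate Sampling rate in Hz; inferred from the median time step when
#'   `NULL`.
#' @param task Task label (e.g. `"normal"`, `"backward"`, `"tandem"`,
#'   `"stance"`).
#' @param device Free-form device identifier.
#' @return An object of class `accel_recording`: a list with elements
#'   `time`, `acc`, `rate`, `task`, `device`.
#' @export
accel_recording <- function(time, acc, rate = NULL, task = "unknown",
                            device = "unknown") {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop("`acc` must have exactly 3 columns (ax, ay, az)")
  if (length(time) != nrow(acc)) stop("`time` and `acc` lengths differ")
  if (anyNA(time) || anyNA(acc)) stop("recording contains missing values")
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing")
  }
  if (is.null(rate)) rate <- infer_rate(time)
  colnames(acc) <- c("ax", "ay", "az")
  structure(
    list(time = as.numeric(time), acc = unname(acc), rate = rate,
         task = task, device = device),
    class = "accel_recording"
  )
}

#' Pelvis and feet position recording
#'
#' Motion-capture style 3-D position streams for the pelvis (centre-of-mass
#' proxy) and both feet. Axis convention: x = anterior-posterior,
#' y = medial-lateral, z = vertical; units metres.
#'
#' @param time Numeric timestamps in seconds, strictly increasing.
#' @param pelvis,left_foot,right_foot Numeric matrices (n x 3), metres.
#' @param rate Sampling rate in Hz; inferred when `NULL`.
#' @param task Task label.
#' @return An object of class `position_recording`.
#' @export
position_recording <- function(time, pelvis, left_foot, right_foot,
                               rate = NULL, task = "unknown") {
  pelvis <- as.matrix(pelvis); left_foot <- as.matrix(left_foot)
  right_foot <- as.matrix(right_foot)
  n <- length(time)
  for (m in list(pelvis, left_foot, right_foot)) {
    if (ncol(m) != 3L || nrow(m) != n) {
      stop("position streams must be n x 3 matrices matching `time`")
    }
  }
  if (anyNA(time) || anyNA(pelvis) || anyNA(left_foot) || anyNA(right_foot)) {
    stop("recording contains missing values")
  }
  if (n > 1L && any(diff(time) <= 0)) stop("`time` must be strictly increasing")
  if (is.null(rate)) rate <- infer_rate(time)
  structure(
    list(time = as.numeric(time), pelvis = unname(pelvis),
         left_foot = unname(left_foot), right_foot = unname(right_foot),
         rate = rate, task = task),
    class = "position_recording"
  )
}

infer_rate <- function(time) {
  if (length(time) < 2L) stop("cannot infer sampling rate from < 2 samples")
  1 / stats::median(diff(time))
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf(
    "<accel_recording> %d samples @ %.1f Hz, %.1f s, task=%s, device=%s\n",
    length(x$time), x$rate, diff(range(x$time)), x$task, x$device))
  invisible(x)
}

#' @export
print.position_recording <- function(x, ...) {
  cat(sprintf("<position_recording> %d samples @ %.1f Hz, %.1f s, task=%s\n",
              length(x$time), x$rate, diff(range(x$time)), x$task))
  invisible(x)
}

# ---- CSV / JSON interchange -------------------------------------------------

#' Read an acceleration CSV (`time_s,ax,ay,az`)
#'
#' @param path File path.
#' @param task,device Labels attached to the returned recording.
#' @return An [accel_recording()].
#' @export
read_accel_csv <- function(path, task = "unknown", device = "unknown") {
  df <- read_numeric_csv(path, c("time_s", "ax", "ay", "az"))
  accel_recording(df$time_s, as.matrix(df[, c("ax", "ay", "az")]),
                  task = task, device = device)
}

#' Write an acceleration recording as CSV
#' @param rec An [accel_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  df <- data.frame(time_s = rec$time, ax = rec$acc[, 1], ay = rec$acc[, 2],
                   az = rec$acc[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

position_cols <- c("time_s",
                   "pelvis_x", "pelvis_y", "pelvis_z",
                   "lfoot_x", "lfoot_y", "lfoot_z",
                   "rfoot_x", "rfoot_y", "rfoot_z")

#' Read a position CSV (`time_s,pelvis_x..z,lfoot_x..z,rfoot_x..z`)
#' @param path File path.
#' @param task Task label.
#' @return A [position_recording()].
#' @export
read_position_csv <- function(path, task = "unknown") {
  df <- read_numeric_csv(path, position_cols)
  position_recording(
    df$time_s,
    as.matrix(df[, c("pelvis_x", "pelvis_y", "pelvis_z")]),
    as.matrix(df[, c("lfoot_x", "lfoot_y", "lfoot_z")]),
    as.matrix(df[, c("rfoot_x", "rfoot_y", "rfoot_z")]),
    task = task)
}

#' Write a position recording as CSV
#' @param rec A [position_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_position_csv <- function(rec, path) {
  stopifnot(inherits(rec, "position_recording"))
  df <- data.frame(rec$time, rec$pelvis, rec$left_foot, rec$right_foot)
  names(df) <- position_cols
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Shared validated numeric CSV reader with line-numbered diagnostics.
read_numeric_csv <- function(path, expected_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), expected_cols)) {
    stop(sprintf("%s: expected header %s but found %s", path,
                 paste(expected_cols, collapse = ","),
                 paste(names(df), collapse = ",")))
  }
  for (cn in names(df)) {
    v <- df[[cn]]
    if (!is.numeric(v)) stop(sprintf("%s: column '%s' is not numeric", path, cn))
    if (anyNA(v)) {
      stop(sprintf("%s: missing/NaN value in column '%s' at data line %d",
                   path, cn, which(is.na(v))[1]))
    }
  }
  t <- df[[1L]]
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stop(sprintf("%s: time not strictly increasing at data line %d",
                 path, bad[1] + 1L))
  }
  df
}

#' Write ground truth as a JSON sidecar
#' @param truth A `ground_truth` list as returned by the generators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path File path.
#' @return A `ground_truth` list.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$lane_boundaries)) {
    x$lane_boundaries <- as.matrix(x$lane_boundaries)
  }
  if (!is.null(x$turn_windows) && length(x$turn_windows)) {
    x$turn_windows <- as.matrix(x$turn_windows)
  }
  structure(x, class = "ground_truth")
}
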