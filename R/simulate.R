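#' Parameters for synthetic gait recordings
#'
#' Defaults reflect the walking task emulated: a 10 m walkway traversed in
#' 6 lanes at ordinary walking speed, cadence 1.7 steps/s with 3% stride
#' variability, gravity on the vertical axis, step bursts well above the
#' noise floor.
#'
#' @param cadence Steps per second.
#' @param stride_cv Coefficient of variation of stride time (unitless).
#' @param mean_velocity Mean walking velocity, m/s.
#' @param step_width Lateral distance between feet, m.
#' @param n_lanes Number of walkway traversals.
#' @param lane_length Walkway length, m.
#' @param burst_amplitude Peak amplitude of the per-step acceleration
#'   burst, m/s^2; must exceed `noise_sd`.
#' @param gravity Constant vertical acceleration offset, m/s^2.
#' @param noise_sd SD of additive Gaussian noise per axis, m/s^2.
#' @param sampling_rate Hz, at least 50.
#' @param seed Integer RNG seed; equal seeds give identical output.
#' @return A validated list of class `gait_sim_params`.
#' @export
gait_sim_params <- function(cadence = 1.7, stride_cv = 0.03,
                            mean_velocity = 1.2, step_width = 0.11,
                            n_lanes = 6, lane_length = 10,
                            burst_amplitude = 3, gravity = 9.81,
                            noise_sd = 0.3, sampling_rate = 100, seed = 1) {
  p <- list(cadence = cadence, stride_cv = stride_cv,
            mean_velocity = mean_velocity, step_width = step_width,
            n_lanes = as.integer(n_lanes), lane_length = lane_length,
            burst_amplitude = burst_amplitude, gravity = gravity,
            noise_sd = noise_sd, sampling_rate = sampling_rate,
            seed = as.integer(seed))
  if (p$cadence <= 0) stop("`cadence` must be positive")
  if (p$stride_cv < 0) stop("`stride_cv` must be non-negative")
  if (p$mean_velocity <= 0) stop("`mean_velocity` must be positive")
  if (p$step_width < 0) stop("`step_width` must be non-negative")
  if (p$n_lanes < 1L) stop("`n_lanes` must be at least 1")
  if (p$lane_length <= 0) stop("`lane_length` must be positive")
  if (p$sampling_rate < 50) stop("`sampling_rate` must be at least 50 Hz")
  if (p$burst_amplitude <= p$noise_sd) {
    stop("`burst_amplitude` must exceed `noise_sd`")
  }
  if (p$noise_sd < 0 || p$gravity < 0) stop("negative noise or gravity")
  structure(p, class = "gait_sim_params")
}

#' Parameters for synthetic stance (sway) recordings
#'
#' @param ap_sd Anteroposterior sway displacement SD, mm.
#' @param ml_sd Mediolateral sway displacement SD, mm.
#' @param vertical_sd Vertical sway displacement SD, mm.
#' @param duration Seconds, in (0, 30] (stance tasks are capped at 30 s).
#' @param drift_rate Linear displacement drift, mm/s (no acceleration
#'   footprint).
#' @param sampling_rate Hz, at least 50.
#' @param gravity Constant vertical acceleration, m/s^2.
#' @param noise_sd Additive accelerometer noise SD per axis, m/s^2.
#' @param seed Integer RNG seed.
#' @return A validated list of class `sway_sim_params`.
#' @export
sway_sim_params <- function(ap_sd = 5, ml_sd = 2, vertical_sd = 1,
                            duration = 30, drift_rate = 0,
                            sampling_rate = 100, gravity = 9.81,
                            noise_sd = 0.05, seed = 1) {
  p <- list(ap_sd = ap_sd, ml_sd = ml_sd, vertical_sd = vertical_sd,
            duration = duration, drift_rate = drift_rate,
            sampling_rate = sampling_rate, gravity = gravity,
            noise_sd = noise_sd, seed = as.integer(seed))
  if (p$duration <= 0 || p$duration > 30) {
    stop("`duration` must be in (0, 30] seconds")
  }
  if (p$ap_sd < 0 || p$ml_sd < 0 || p$vertical_sd < 0 || p$noise_sd < 0) {
    stop("sway scales and noise must be non-negative")
  }
  if (p$sampling_rate < 50) stop("`sampling_rate` must be at least 50 Hz")
  structure(p, class = "sway_sim_params")
}

TURN_SECONDS <- 2
BURST_WIDTH_S <- 0.15

# Draw per-lane step times. Inter-step intervals are Gaussian with mean
# 1/cadence and SD stride_cv/cadence (truncated to stay positive); stride
# times and the MSI are computed within lanes only, never across turns.
draw_step_times <- function(p) {
  mean_inter <- 1 / p$cadence
  sd_inter <- p$stride_cv * mean_inter
  lane_dur <- p$lane_length / p$mean_velocity
  lane_starts <- (seq_len(p$n_lanes) - 1L) * (lane_dur + TURN_SECONDS)
  lane_ends <- lane_starts + lane_dur
  by_lane <- vector("list", p$n_lanes)
  for (i in seq_len(p$n_lanes)) {
    t <- lane_starts[i] + 0.5 * mean_inter
    times <- numeric(0)
    repeat {
      if (t > lane_ends[i] - 0.25 * mean_inter) break
      times <- c(times, t)
      d <- if (sd_inter > 0) stats::rnorm(1, mean_inter, sd_inter)
           else mean_inter
      d <- max(d, 0.3 * mean_inter)
      t <- t + d
    }
    by_lane[[i]] <- times
  }
  inter <- unlist(lapply(by_lane, function(t) if (length(t) > 1) diff(t)))
  stride <- unlist(lapply(by_lane, function(t) {
    if (length(t) < 3) return(NULL)
    d <- diff(t); d[-length(d)] + d[-1L]
  }))
  turn_windows <- if (p$n_lanes > 1L) {
    cbind(lane_ends[-p$n_lanes], lane_starts[-1L])
  } else matrix(numeric(0), ncol = 2L)
  list(by_lane = by_lane,
       step_times = unlist(by_lane),
       inter_step_times = inter, stride_times = stride,
       lane_boundaries = cbind(lane_starts, lane_ends),
       turn_windows = turn_windows,
       total_duration = lane_ends[p$n_lanes])
}

make_ground_truth <- function(st, p) {
  structure(
    list(step_times = st$step_times,
         stride_times = st$stride_times,
         msi = mean(st$stride_times),
         true_cadence = 1 / mean(st$inter_step_times),
         true_velocity = p$mean_velocity,
         true_step_width = p$step_width,
         true_ap_sway = NA_real_, true_ml_sway = NA_real_,
         lane_boundaries = unname(st$lane_boundaries),
         turn_windows = unname(st$turn_windows),
         step_times_by_lane = st$by_lane),
    class = "ground_truth")
}

# Raised-cosine bump of width `w` centred at t0, added in place.
add_bump <- function(signal, time, t0, amp, w) {
  idx <- which(time >= t0 - w / 2 & time <= t0 + w / 2)
  if (length(idx)) {
    signal[idx] <- signal[idx] +
      amp * 0.5 * (1 + cos(2 * pi * (time[idx] - t0) / w))
  }
  signal
}

#' Generate a synthetic smartphone gait recording
#'
#' The vertical axis carries the constant gravitational offset plus one
#' band-limited raised-cosine burst (width 0.15 s) per step at the
#' ground-truth step times; all axes carry additive Gaussian noise. Between
#' lanes, 2 s turn segments of low-amplitude (0.3 x burst) irregular signal
#' are inserted and flagged in the ground truth, so turn-removal logic can
#' be exercised. Identical seeds give identical output.
#'
#' @param params A [gait_sim_params()].
#' @return A list with `recording` ([accel_recording()]) and `truth`
#'   (class `ground_truth`: step times, stride times, MSI, cadence, lane
#'   boundaries, turn windows).
#' @export
generate_gait_accel <- function(params) {
  stopifnot(inherits(params, "gait_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    st <- draw_step_times(p)
    time <- seq(0, st$total_duration, by = 1 / p$sampling_rate)
    n <- length(time)
    ax <- stats::rnorm(n, 0, p$noise_sd)
    ay <- stats::rnorm(n, 0, p$noise_sd)
    az <- p$gravity + stats::rnorm(n, 0, p$noise_sd)
    for (t0 in st$step_times) {
      az <- add_bump(az, time, t0, p$burst_amplitude, BURST_WIDTH_S)
    }
    if (nrow(st$turn_windows)) {
      for (k in seq_len(nrow(st$turn_windows))) {
        idx <- which(time >= st$turn_windows[k, 1] &
                       time < st$turn_windows[k, 2])
        if (!length(idx)) next
        ph <- stats::runif(2, 0, 2 * pi)
        tt <- time[idx]
        az[idx] <- az[idx] + 0.3 * p$burst_amplitude *
          (0.6 * sin(2 * pi * 0.9 * tt + ph[1]) +
             0.4 * sin(2 * pi * 1.7 * tt + ph[2]))
      }
    }
    rec <- accel_recording(time, cbind(ax, ay, az), rate = p$sampling_rate,
                           task = "gait", device = "synthetic-smartphone")
    list(recording = rec, truth = make_ground_truth(st, p))
  })
}

#' Generate a synthetic stance (sway) accelerometer recording
#'
#' Sway displacement per axis is an analytic sum of sinusoids with random
#' frequencies in 1.2-2.0 Hz (band-limited, inside the 0.8-20 Hz analysis
#' passband) scaled to the requested displacement SD; the recorded
#' acceleration is its exact second derivative plus gravity (vertical) and
#' Gaussian noise. A linear drift adds to the displacement but leaves no
#' acceleration footprint.
#'
#' @param params A [sway_sim_params()].
#' @return A list with `recording` ([accel_recording()]) and `truth`
#'   (carries `true_ap_sway`/`true_ml_sway` in mm and the exact
#'   `displacement_mm` matrix).
#' @export
generate_balance_accel <- function(params) {
  stopifnot(inherits(params, "sway_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    time <- seq(0, p$duration, by = 1 / p$sampling_rate)
    n <- length(time)
    K <- 8L
    one_axis <- function(target_sd_mm) {
      f <- stats::runif(K, 1.2, 2.0)
      ph <- stats::runif(K, 0, 2 * pi)
      a <- abs(stats::rnorm(K, 1, 0.3))
      d0 <- rowSums(sapply(seq_len(K), function(k) {
        a[k] * sin(2 * pi * f[k] * time + ph[k])
      }))
      if (target_sd_mm == 0 || stats::sd(d0) == 0) {
        return(list(disp = numeric(n), acc = numeric(n)))
      }
      s <- target_sd_mm / stats::sd(d0)
      acc0 <- rowSums(sapply(seq_len(K), function(k) {
        -a[k] * (2 * pi * f[k])^2 * sin(2 * pi * f[k] * time + ph[k])
      }))
      list(disp = s * d0, acc = s * acc0 / 1000)  # mm -> m/s^2
    }
    axx <- one_axis(p$ap_sd)
    axy <- one_axis(p$ml_sd)
    axz <- one_axis(p$vertical_sd)
    acc <- cbind(axx$acc + stats::rnorm(n, 0, p$noise_sd),
                 axy$acc + stats::rnorm(n, 0, p$noise_sd),
                 axz$acc + p$gravity + stats::rnorm(n, 0, p$noise_sd))
    disp <- cbind(axx$disp + p$drift_rate * time, axy$disp, axz$disp)
    rec <- accel_recording(time, acc, rate = p$sampling_rate,
                           task = "stance", device = "synthetic-smartphone")
    truth <- structure(
      list(true_ap_sway = p$ap_sd, true_ml_sway = p$ml_sd,
           true_vertical_sway = p$vertical_sd, duration = p$duration,
           displacement_mm = disp),
      class = "ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' Generate a synthetic mocap walking recording
#'
#' The pelvis progresses at constant speed along alternating +x/-x lanes
#' with a small lateral sinusoid and a vertical COM oscillation peaking
#' once per step (at the same ground-truth step times as the paired
#' accelerometer recording when the same parameters/seed are used). Feet
#' travel at constant lateral offset `+/- step_width/2` with a vertical
#' bump per stride whose minima mark mid-stance. Each lane is rotated in
#' the x-y plane by `heading_error_deg` about its start to simulate IMU
#' heading drift; 2 s turns connect the lanes.
#'
#' @param params A [gait_sim_params()].
#' @param heading_error_deg Per-lane heading drift in degrees, |.| < 90.
#' @param rate Position sampling rate in Hz (mocap systems typically 60).
#' @return A list with `recording` ([position_recording()]) and `truth`.
#' @export
generate_mocap_walk <- function(params, heading_error_deg = 0, rate = 60) {
  stopifnot(inherits(params, "gait_sim_params"))
  if (abs(heading_error_deg) >= 90) stop("|heading_error_deg| must be < 90")
  p <- params
  # Lateral pelvis oscillation is kept sub-millimetre so lanes progress
  # straight: per-lane net y-displacement stays below 1 mm at zero heading
  # error regardless of where the end exclusion clips the lane.
  z0 <- 1.0; a_com <- 0.02; lat_amp <- 5e-4; foot_h <- 0.08
  theta <- heading_error_deg * pi / 180

  withr::with_seed(p$seed, {
    st <- draw_step_times(p)
    time <- seq(0, st$total_duration, by = 1 / rate)
    n <- length(time)
    lane_dur <- p$lane_length / p$mean_velocity
    lb <- st$lane_boundaries

    pelvis <- matrix(0, n, 3); lfoot <- matrix(0, n, 3)
    rfoot <- matrix(0, n, 3)

    # piecewise-cosine vertical COM: peak exactly at each step time
    com_z <- function(tt, steps) {
      if (length(steps) < 2L) return(rep(z0 + a_com, length(tt)))
      k <- findInterval(tt, steps)
      k <- pmin(pmax(k, 1L), length(steps) - 1L)
      period <- steps[k + 1L] - steps[k]
      z0 + a_com * cos(2 * pi * (tt - steps[k]) / period)
    }
    # per-foot vertical bump between consecutive stance times of that foot
    foot_z <- function(tt, stances) {
      if (length(stances) < 2L) return(numeric(length(tt)))
      z <- numeric(length(tt))
      inside <- tt >= stances[1] & tt <= stances[length(stances)]
      k <- findInterval(tt[inside], stances)
      k <- pmin(pmax(k, 1L), length(stances) - 1L)
      period <- stances[k + 1L] - stances[k]
      z[inside] <- foot_h * 0.5 *
        (1 - cos(2 * pi * (tt[inside] - stances[k]) / period))
      z
    }

    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)),
                2L, 2L, byrow = TRUE)
    # Lanes are built in a local frame (progress along +/- x, small lateral
    # sinusoid, feet offset +/- step_width/2), rotated by the heading error
    # and chained onto the previous lane's end (plus a small lateral turn
    # offset), so turns stay at the x-extrema of the trajectory.
    origin <- c(0, 0)
    for (i in seq_len(p$n_lanes)) {
      dir <- if (i %% 2L == 1L) 1 else -1
      idx <- which(time >= lb[i, 1] & time <= lb[i, 2])
      tt <- time[idx]
      u <- (tt - lb[i, 1]) * p$mean_velocity
      steps_i <- st$by_lane[[i]]
      lx <- dir * u
      ly <- lat_amp * sin(2 * pi * (p$cadence / 2) * (tt - lb[i, 1]))
      pz <- com_z(tt, steps_i)
      odd <- steps_i[seq_along(steps_i) %% 2L == 1L]
      even <- steps_i[seq_along(steps_i) %% 2L == 0L]
      lz <- foot_z(tt, odd); rz <- foot_z(tt, even)
      place <- function(xl, yl) {
        m <- cbind(xl, yl) %*% t(R)
        cbind(m[, 1] + origin[1], m[, 2] + origin[2])
      }
      pxy <- place(lx, ly)
      lxy <- place(lx, rep(p$step_width / 2, length(tt)))
      rxy <- place(lx, rep(-p$step_width / 2, length(tt)))
      pelvis[idx, ] <- cbind(pxy, pz)
      lfoot[idx, ] <- cbind(lxy, lz)
      rfoot[idx, ] <- cbind(rxy, rz)
      origin <- pxy[nrow(pxy), ] + c(0, 0.3)  # lateral shift during the turn
    }

    # turns: cosine blend between the (rotated) lane endpoints, with a
    # lateral bulge so the pelvis leaves the walking line
    if (nrow(st$turn_windows)) {
      for (k in seq_len(nrow(st$turn_windows))) {
        idx <- which(time > st$turn_windows[k, 1] &
                       time < st$turn_windows[k, 2])
        if (!length(idx)) next
        i0 <- max(which(time <= st$turn_windows[k, 1]))
        i1 <- min(which(time >= st$turn_windows[k, 2]))
        tau <- (time[idx] - time[i0]) / (time[i1] - time[i0])
        s <- (1 - cos(pi * tau)) / 2
        bulge <- 0.4 * sin(pi * tau)
        blend <- function(m) {
          out <- outer(1 - s, m[i0, ]) + outer(s, m[i1, ])
          out[, 2] <- out[, 2] + bulge
          out
        }
        pelvis[idx, ] <- blend(pelvis)
        lfoot[idx, ] <- blend(lfoot)
        rfoot[idx, ] <- blend(rfoot)
      }
    }

    rec <- position_recording(time, pelvis, lfoot, rfoot, rate = rate,
                              task = "gait")
    truth <- make_ground_truth(st, p)
    truth$heading_error_deg <- heading_error_deg
    list(recording = rec, truth = truth)
  })
}

#' Generate a paired two-visit study with configurable training effects
#'
#' Each subject gets a random baseline parameter set (between-subject
#' log-normal variation around the base parameters). Nominal second-visit
#' (T2) parameters are the first-visit (T1) ones scaled exactly by the
#' configured multiplicative effects; the parameters actually realized in
#' each visit's recording additionally carry within-subject log-normal
#' variation (`within_cv`), emulating day-to-day fluctuation.
#'
#' @param n_subjects Number of subjects, at least 2.
#' @param effects Named list of multiplicative T1 -> T2 effects; recognised
#'   names: `cadence`, `velocity`, `step_width`. Unlisted variables get
#'   effect 1.
#' @param base A [gait_sim_params()] giving the population-level task
#'   set-up.
#' @param systems Which recordings to synthesize per visit:
#'   `"smartphone"` (accelerometer) and/or `"mocap"` (positions).
#' @param between_cv Between-subject CV of baseline parameters.
#' @param within_cv Within-subject (visit-to-visit) CV of realized
#'   parameters.
#' @param task Task label used in file naming.
#' @param seed Integer master seed; the whole study is reproducible.
#' @return Object of class `paired_study`: list with `params` (data frame
#'   of nominal and realized parameters per subject x visit), `recordings`
#'   (`recordings[[subject]][[visit]]` with elements `accel`, `mocap`,
#'   `truth`), `effects`, `n_subjects`, `seed`.
#' @export
generate_paired_study <- function(n_subjects = 21, effects = list(),
                                  base = gait_sim_params(),
                                  systems = "smartphone",
                                  between_cv = 0.05, within_cv = 0.02,
                                  task = "normal", seed = 1) {
  if (n_subjects < 2L) stop("`n_subjects` must be at least 2")
  eff <- list(cadence = 1, velocity = 1, step_width = 1)
  for (nm in names(effects)) {
    if (!nm %in% names(eff)) stop("unknown effect variable: ", nm)
    eff[[nm]] <- effects[[nm]]
  }
  withr::with_seed(seed, {
    rows <- list(); recs <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      mult <- exp(stats::rnorm(3, 0, between_cv))
      nominal_t1 <- c(cadence = base$cadence * mult[1],
                      velocity = base$mean_velocity * mult[2],
                      step_width = base$step_width * mult[3])
      nominal_t2 <- nominal_t1 * c(eff$cadence, eff$velocity, eff$step_width)
      recs[[s]] <- list()
      for (visit in c("T1", "T2")) {
        nominal <- if (visit == "T1") nominal_t1 else nominal_t2
        realized <- nominal * exp(stats::rnorm(3, 0, within_cv))
        rec_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        pv <- gait_sim_params(
          cadence = realized["cadence"], stride_cv = base$stride_cv,
          mean_velocity = realized["velocity"],
          step_width = realized["step_width"], n_lanes = base$n_lanes,
          lane_length = base$lane_length,
          burst_amplitude = base$burst_amplitude, gravity = base$gravity,
          noise_sd = base$noise_sd, sampling_rate = base$sampling_rate,
          seed = rec_seed)
        entry <- list(params = pv)
        if ("smartphone" %in% systems) {
          g <- generate_gait_accel(pv)
          entry$accel <- g$recording
          entry$truth <- g$truth
        }
        if ("mocap" %in% systems) {
          m <- generate_mocap_walk(pv)
          entry$mocap <- m$recording
          if (is.null(entry$truth)) entry$truth <- m$truth
        }
        recs[[s]][[visit]] <- entry
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, visit = visit,
          nominal_cadence = unname(nominal["cadence"]),
          nominal_velocity = unname(nominal["velocity"]),
          nominal_step_width = unname(nominal["step_width"]),
          realized_cadence = unname(realized["cadence"]),
          realized_velocity = unname(realized["velocity"]),
          realized_step_width = unname(realized["step_width"]),
          seed = rec_seed)
      }
    }
    structure(
      list(n_subjects = n_subjects, effects = eff,
           params = do.call(rbind, rows), recordings = recs,
           task = task, seed = seed),
      class = "paired_study")
  })
}

#' Write a paired study to disk as CSV recordings plus truth sidecars
#'
#' File naming follows `subject_task_visit_system.csv`, the convention
#' [run_pipeline()] expects; ground truth goes to matching `.truth.json`
#' sidecars.
#'
#' @param study A `paired_study` from [generate_paired_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "paired_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_len(study$n_subjects)) {
    for (visit in names(study$recordings[[s]])) {
      e <- study$recordings[[s]][[visit]]
      stem <- sprintf("S%02d_%s_%s", s, study$task, visit)
      if (!is.null(e$accel)) {
        write_accel_csv(e$accel,
                        file.path(dir, paste0(stem, "_smartphone.csv")))
      }
      if (!is.null(e$mocap)) {
        write_position_csv(e$mocap,
                           file.path(dir, paste0(stem, "_mocap.csv")))
      }
      if (!is.null(e$truth)) {
        tr <- e$truth
        tr$step_times_by_lane <- NULL
        write_ground_truth(tr, file.path(dir, paste0(stem, ".truth.json")))
      }
    }
  }
  invisible(dir)
}
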