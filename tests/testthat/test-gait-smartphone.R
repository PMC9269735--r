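test_that("detector defaults match the calibrated task settings", {
  expect_equal(detector_defaults("normal"), list(k_sd = 2.3, min_dist = 0.38))
  expect_equal(detector_defaults("backward"), list(k_sd = 2.3, min_dist = 0.38))
  expect_equal(detector_defaults("tandem"), list(k_sd = 2.7, min_dist = 0.42))
})

test_that("constant signal yields no step peaks", {
  t <- seq(0, 10, by = 0.01)
  ev <- detect_steps(t, rep(1, length(t)), k_sd = 2.3, min_dist = 0.38)
  expect_length(ev, 0)
})

test_that("detection on noiseless bursts recovers step times within one sample", {
  g <- generate_gait_accel(gait_sim_params(cadence = 2.0, stride_cv = 0,
                                           noise_sd = 0, seed = 1))
  fn <- filtered_norm(g$recording)
  lb <- g$truth$lane_boundaries
  for (i in seq_len(nrow(lb))) {
    keep <- fn$time >= lb[i, 1] & fn$time < lb[i, 2]
    ev <- detect_steps(fn$time[keep], fn$norm[keep], 2.3, 0.38)
    truth_i <- g$truth$step_times_by_lane[[i]]
    expect_equal(length(ev), length(truth_i))
    expect_lt(max(abs(as.numeric(ev) - truth_i)), 0.01 + 1e-9)
  }
})

test_that("stride metrics follow the two-steps-per-stride definition", {
  sm <- stride_metrics(c(0, 0.5, 1.0, 1.5, 2.0))
  expect_equal(sm$inter_step_times, rep(0.5, 4))
  expect_equal(sm$msi, 1.0)
  expect_equal(sm$cadence, 2.0)

  sm2 <- stride_metrics(c(0, 0.4, 1.0))
  expect_equal(sm2$stride_times, 1.0)
  expect_equal(sm2$msi, 1.0)
  expect_equal(sm2$cadence, 2.0)

  expect_error(stride_metrics(c(0, 1)), "insufficient")

  set.seed(10)
  pk <- cumsum(runif(200, 0.3, 0.9))
  sm3 <- stride_metrics(pk)
  inter <- sapply(2:200, function(i) pk[i] - pk[i - 1])
  stride <- sapply(3:200, function(i) pk[i] - pk[i - 2])
  expect_equal(sm3$inter_step_times, inter)
  expect_equal(sm3$stride_times, stride)
  expect_equal(sm3$msi, mean(stride))
  expect_equal(sm3$cadence, 1 / mean(inter))
})

test_that("detect_steps equals the exhaustive enumeration oracle on random signals", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(20:200, 1)
    t <- seq(0, by = 0.01, length.out = n)
    v <- rnorm(n)
    k <- runif(1, 0.2, 2.5)
    d <- runif(1, 0.02, (n - 1) * 0.01 / 2)  # valid for the series length
    expect_equal(as.numeric(detect_steps(t, v, k, d)),
                 oracle_detect(t, v, k, d))
  }
})

test_that("detection is shift-equivariant and amplitude-scale invariant", {
  g <- generate_gait_accel(gait_sim_params(seed = 6))
  fn <- filtered_norm(g$recording)
  base <- as.numeric(detect_steps(fn$time, fn$norm))
  shifted <- as.numeric(detect_steps(fn$time + 12.5, fn$norm))
  expect_equal(shifted, base + 12.5)
  for (c in c(0.2, 3, 100)) {
    expect_equal(as.numeric(detect_steps(fn$time, c * fn$norm)), base)
  }
})

test_that("raising the threshold or spacing never adds peaks", {
  set.seed(31)
  for (i in 1:10) {
    n <- 400
    t <- seq(0, by = 0.01, length.out = n)
    v <- abs(rnorm(n)) + sin(2 * pi * 2 * t)
    n_by_k <- sapply(seq(0.5, 3, by = 0.5), function(k) {
      length(detect_steps(t, v, k_sd = k, min_dist = 0.1))
    })
    expect_true(all(diff(n_by_k) <= 0))
    n_by_d <- sapply(seq(0.05, 0.5, by = 0.05), function(d) {
      length(detect_steps(t, v, k_sd = 1, min_dist = d))
    })
    expect_true(all(diff(n_by_d) <= 0))
  }
})

test_that("detected cadence tracks ground truth within 2% across seeds", {
  errs <- sapply(1:20, function(seed) {
    p <- gait_sim_params(cadence = 1.7, stride_cv = 0.03, seed = seed)
    g <- generate_gait_accel(p)
    ft <- smartphone_gait_features(g$recording,
                                   windows = g$truth$lane_boundaries,
                                   compute_velocity = FALSE)
    abs(ft$cadence - g$truth$true_cadence) / g$truth$true_cadence
  })
  expect_lt(median(errs), 0.02)
})

test_that("a single-cell grid is its own optimum and the default grid matches the protocol", {
  gs <- grid_spec()
  expect_equal(range(gs$k_sd), c(1.5, 3.0))
  expect_equal(range(gs$min_dist), c(0.20, 0.44))
  expect_equal(length(gs$k_sd), 16)
  expect_equal(length(gs$min_dist), 13)

  recs <- list(); tmsi <- numeric(3); wins <- list()
  for (i in 1:3) {
    g <- generate_gait_accel(gait_sim_params(cadence = 1.4 + 0.3 * i,
                                             n_lanes = 2, seed = 50 + i))
    recs[[i]] <- g$recording; tmsi[i] <- g$truth$msi
    wins[[i]] <- g$truth$lane_boundaries
  }
  gr <- calibrate_grid(recs, tmsi, grid = grid_spec(k_sd = 2.3,
                                                    min_dist = 0.38),
                       windows_list = wins)
  expect_equal(gr$optimum$k_sd, 2.3)
  expect_equal(gr$optimum$min_dist, 0.38)
  expect_equal(nrow(gr$surface), 1)
  expect_error(calibrate_grid(recs[1:2], tmsi[1:2]), "at least 3")
})

test_that("velocity of a silent recording is zero and short windows are flagged", {
  t <- seq(0, 10, by = 0.01)
  rec <- accel_recording(t, matrix(0, length(t), 3))
  expect_equal(as.numeric(estimate_velocity(rec)), 0)
  short <- accel_recording(seq(0, 3, by = 0.01),
                           matrix(0, 301, 3))
  v <- estimate_velocity(short)
  expect_true(isTRUE(attr(v, "unstable")))
})

test_that("pipeline velocity agrees with a single-pass integration oracle within 5%", {
  g <- generate_gait_accel(gait_sim_params(n_lanes = 2, seed = 14))
  rec <- g$recording
  v_pkg <- as.numeric(estimate_velocity(rec))

  # oracle: rectangle-rule cumulative sums with the same interleaved
  # band-pass, path length over duration
  bp <- function(m) bandpass(m, rec$rate)
  csum <- function(m) apply(m, 2, function(col) cumsum(col) / rec$rate)
  disp <- bp(csum(bp(csum(bp(rec$acc)))))
  v_oracle <- sum(sqrt(rowSums(diff(disp)^2))) / diff(range(rec$time))
  expect_lt(abs(v_pkg - v_oracle) / v_oracle, 0.05)
})
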