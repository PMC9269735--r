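test_that("generators are deterministic under a fixed seed", {
  p <- gait_sim_params(seed = 42)
  expect_identical(generate_gait_accel(p), generate_gait_accel(p))
  expect_identical(generate_mocap_walk(p, 10), generate_mocap_walk(p, 10))
  sp <- sway_sim_params(seed = 42)
  expect_identical(generate_balance_accel(sp), generate_balance_accel(sp))
  expect_false(identical(generate_gait_accel(p),
                         generate_gait_accel(gait_sim_params(seed = 43))))
})

test_that("zero stride variability gives exactly regular inter-step times", {
  g <- generate_gait_accel(gait_sim_params(cadence = 2.0, stride_cv = 0,
                                           seed = 1))
  inter <- unlist(lapply(g$truth$step_times_by_lane, diff))
  expect_equal(inter, rep(0.5, length(inter)), tolerance = 1e-12)
})

test_that("ground truth is internally consistent", {
  for (seed in c(1, 7, 23)) {
    g <- generate_gait_accel(gait_sim_params(seed = seed))
    tr <- g$truth
    expect_equal(tr$msi, mean(tr$stride_times), tolerance = 1e-12)
    inter <- unlist(lapply(tr$step_times_by_lane, diff))
    expect_lt(abs(tr$true_cadence * mean(inter) - 1), 1e-9)
    expect_true(all(diff(tr$step_times) > 0))
    expect_equal(nrow(tr$lane_boundaries), 6)
  }
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(gait_sim_params(cadence = 0), "cadence")
  expect_error(gait_sim_params(sampling_rate = 20), "sampling_rate")
  expect_error(gait_sim_params(burst_amplitude = 0.1, noise_sd = 0.3),
               "exceed")
  expect_error(sway_sim_params(duration = 31), "duration")
  expect_error(generate_mocap_walk(gait_sim_params(), 95), "heading")
})

test_that("noiseless filtered-norm maxima land within one sample of true step times", {
  p <- gait_sim_params(noise_sd = 0, stride_cv = 0.02, seed = 3)
  g <- generate_gait_accel(p)
  fn <- filtered_norm(g$recording)
  ev <- smartphone_gait_features(g$recording,
                                 windows = g$truth$lane_boundaries,
                                 compute_velocity = FALSE)
  dt <- 1 / p$sampling_rate
  for (t0 in ev$step_times) {
    expect_lt(min(abs(g$truth$step_times - t0)), dt + 1e-9)
  }
})

test_that("stance generator: zero sway and noise leaves gravity only", {
  b <- generate_balance_accel(sway_sim_params(ap_sd = 0, ml_sd = 0,
                                              vertical_sd = 0, noise_sd = 0))
  expect_true(all(abs(b$recording$acc[, 1:2]) < 1e-12))
  expect_true(all(abs(b$recording$acc[, 3] - 9.81) < 1e-12))
})

test_that("swapping AP and ML sway scales swaps the ground-truth fields", {
  a <- generate_balance_accel(sway_sim_params(ap_sd = 5, ml_sd = 2, seed = 8))
  b <- generate_balance_accel(sway_sim_params(ap_sd = 2, ml_sd = 5, seed = 8))
  expect_equal(a$truth$true_ap_sway, b$truth$true_ml_sway)
  expect_equal(a$truth$true_ml_sway, b$truth$true_ap_sway)
})

test_that("recovered sway displacement SD is within 15% of the configured scales", {
  b <- generate_balance_accel(sway_sim_params(ap_sd = 5, ml_sd = 2,
                                              vertical_sd = 1, noise_sd = 0,
                                              seed = 2))
  d <- displacement_from_accel(b$recording)
  sds <- apply(d$disp, 2, sd)
  expect_lt(abs(sds[1] - 5) / 5, 0.15)
  expect_lt(abs(sds[2] - 2) / 2, 0.15)
})

test_that("mocap lanes are straight at zero heading error and rotated otherwise", {
  p <- gait_sim_params(noise_sd = 0.3, seed = 12)
  m0 <- generate_mocap_walk(p, heading_error_deg = 0)
  lanes <- split_lanes(m0$recording)
  expect_length(lanes, 6)
  for (l in lanes) {
    dy <- abs(l$pelvis[nrow(l$pelvis), 2] - l$pelvis[1, 2])
    expect_lt(dy, 1e-3)  # < 1 mm
  }
  m17 <- generate_mocap_walk(p, heading_error_deg = 17)
  l1 <- split_lanes(m17$recording)[[1]]
  net <- l1$pelvis[nrow(l1$pelvis), 1:2] - l1$pelvis[1, 1:2]
  expect_lt(abs(atan2(net[2], net[1]) * 180 / pi - 17), 0.5)
})

test_that("mocap lane boundaries match generator ground truth within 0.2 s", {
  m <- generate_mocap_walk(gait_sim_params(seed = 21))
  lanes <- split_lanes(m$recording)
  lb <- m$truth$lane_boundaries
  expect_length(lanes, nrow(lb))
  for (i in seq_along(lanes)) {
    expect_gte(min(lanes[[i]]$time), lb[i, 1] - 0.2)
    expect_lte(max(lanes[[i]]$time), lb[i, 2] + 0.2)
  }
})

test_that("paired study applies effects to nominal parameters exactly", {
  st <- generate_paired_study(n_subjects = 4, effects = list(),
                              base = gait_sim_params(n_lanes = 1),
                              systems = character(0), seed = 5)
  p1 <- st$params[st$params$visit == "T1", ]
  p2 <- st$params[st$params$visit == "T2", ]
  expect_equal(p1$nominal_cadence, p2$nominal_cadence)
  expect_equal(p1$nominal_velocity, p2$nominal_velocity)

  st2 <- generate_paired_study(n_subjects = 21,
                               effects = list(velocity = 1.05),
                               base = gait_sim_params(n_lanes = 1),
                               systems = character(0), seed = 5)
  q1 <- st2$params[st2$params$visit == "T1", ]
  q2 <- st2$params[st2$params$visit == "T2", ]
  expect_equal(mean(q2$nominal_velocity / q1$nominal_velocity), 1.05,
               tolerance = 1e-12)
  expect_error(generate_paired_study(n_subjects = 1), "at least 2")
  expect_error(generate_paired_study(effects = list(bogus = 2)), "unknown")
})

test_that("paired study is reproducible and pairs every T2 with a T1", {
  a <- generate_paired_study(n_subjects = 3,
                             base = gait_sim_params(n_lanes = 2), seed = 9)
  b <- generate_paired_study(n_subjects = 3,
                             base = gait_sim_params(n_lanes = 2), seed = 9)
  expect_identical(a, b)
  for (s in 1:3) {
    expect_setequal(names(a$recordings[[s]]), c("T1", "T2"))
  }
})
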