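test_that("primary measures: collinear joints and static pairs", {
  rec <- still_recording(4)
  seg <- maneuver_segment("RT", 0, n_frames(rec))
  pm <- primary_measures(seg, rec,
                         pairs = list(c("SHOULDER_L", "SHOULDER_R")),
                         triplets = list(c("HIP_L", "KNEE_L", "ANKLE_L")))
  # the canonical standing leg is collinear: knee angle 180 deg
  expect_equal(unname(pm$angles[[1]]), rep(180, n_frames(rec)),
               tolerance = 1e-8)
  # static joints: constant distance, zero angular velocity
  expect_equal(diff(range(pm$distances[[1]])), 0, tolerance = 1e-12)
  expect_equal(max(abs(pm$angular_velocities[[1]])), 0, tolerance = 1e-6)
})

test_that("angular velocity matches a programmed rotation rate", {
  # rotate the left arm (shoulder->hand) about the shoulder at 30 deg/s
  rate <- 30; n <- 90
  t <- (0:(n - 1)) / rate
  P0 <- canonical_skeleton(1.70)
  sh <- P0["SHOULDER_L", ]
  r <- 0.5
  ang <- 30 * t * pi / 180
  rec <- still_recording(3, overrides = list(
    HAND_L_x = sh[1] + r * cos(ang),
    HAND_L_y = sh[2] - r * sin(ang)))
  seg <- maneuver_segment("RT", 0, n)
  pm <- primary_measures(seg, rec,
                         triplets = list(c("HAND_L", "SHOULDER_L", "HIP_CENTER")),
                         smooth_width = 1)
  av <- pm$angular_velocities[[1]]
  expect_equal(mean(abs(av[5:(n - 5)])), 30, tolerance = 0.1 / 30)
})

test_that("perfect noise-free reaches give zero accuracy error", {
  tf <- compute_trial_features(sim_protocol(seed = 3)$recording)
  expect_lt(tf$fnt_acc_L, 0.002)
  expect_lt(tf$fnt_acc_R, 0.002)
  expect_lt(tf$fnt_acc_sd_L, 0.002)
  expect_equal(tf$fnt_drop_L, 0, tolerance = 0.1)
})

test_that("programmed endpoint misses are recovered from ground truth", {
  sim <- sim_protocol(seed = 5, jitter = 0.03)
  tf <- compute_trial_features(sim$recording)
  reps <- sim$truth$details$FNT$reps
  miss <- vapply(reps, `[[`, numeric(1), "miss")
  side <- vapply(reps, `[[`, character(1), "side")
  # the measured minimum over the smoothed path sits slightly below the
  # programmed endpoint miss, by construction of the minimum
  expect_lt(abs(tf$fnt_acc_L - mean(miss[side == "L"])), 0.012)
  expect_lt(abs(tf$fnt_acc_R - mean(miss[side == "R"])), 0.012)
  expect_lt(abs(tf$fnt_acc_sd_L - sd(miss[side == "L"])), 0.012)
})

test_that("constant-speed reach yields distance/time as the speed", {
  # hand moves 0.6 m toward the nose proxy in 1 s, then back, 3 times
  rate <- 30
  P0 <- canonical_skeleton(1.70)
  h0 <- P0["HAND_L", ]
  nose <- P0["HEAD", ] + c(0, 0, -0.10)
  dir <- (nose - h0) / sqrt(sum((nose - h0)^2))
  one_rep <- c(seq(0, 1, length.out = rate),
               seq(1, 0, length.out = rate),
               rep(0, 15))
  s <- c(rep(0, 30), rep(one_rep, 3), rep(0, 30))
  n <- length(s)
  rec <- still_recording(n / rate, overrides = list(
    HAND_L_x = h0[1] + 0.6 * s * dir[1],
    HAND_L_y = h0[2] + 0.6 * s * dir[2],
    HAND_L_z = h0[3] + 0.6 * s * dir[3]))
  seg <- maneuver_segment("FNT", 0, n)
  d <- sqrt(rowSums((joint_track(rec, "HAND_L") -
                       matrix(nose, n, 3, byrow = TRUE))^2))
  seg <- split_repetitions(seg, rec, d, 3, side = "L")
  f <- fnt_features(seg, rec, "L")
  expect_equal(f$speed, 0.6, tolerance = 0.05)
})

test_that("hand oscillation range is twice the amplitude", {
  a <- 0.04
  n <- 360; t <- (0:(n - 1)) / 30
  y0 <- canonical_skeleton(1.70)["HAND_L", "y"]
  rec <- still_recording(12, overrides = list(
    HAND_L_y = y0 + a * sin(2 * pi * 1 * t)))
  rt <- maneuver_segment("RT", 0, 180)
  tt <- maneuver_segment("TT", 180, 360)
  # statics on a still T-pose skeleton are exactly zero...
  PT <- motorkin:::t_pose(canonical_skeleton(1.70), 1.70)
  st0 <- static_features(rt, tt, still_recording(12, pose = PT))
  expect_equal(st0$inv_range_L, 0)
  expect_equal(st0$inv_speed_L, 0)
  expect_equal(st0$stab_range, 0)
  # ...and an oscillating hand spans 2a (arms are below the shoulders
  # here, so measure through cloud_diameter on the RT window directly)
  # discretization at 30 Hz samples just inside the sinusoid peaks
  rng <- motorkin:::cloud_diameter(rec, "HAND_L", 1:180)
  expect_equal(rng, 2 * a, tolerance = 0.01)
})

test_that("noise floor makes static ranges strictly positive", {
  sim <- sim_protocol(seed = 3, noisy = TRUE)
  tf <- compute_trial_features(sim$recording)
  expect_gt(tf$inv_range_L, 0)
  expect_gt(tf$inv_speed_L, 0)
  expect_gt(tf$stab_range, 0)
})

test_that("step features recover programmed angles and nulls", {
  tf <- compute_trial_features(sim_protocol(seed = 3)$recording)
  expect_equal(tf$sst_angle_L, 30, tolerance = 0.1)
  expect_equal(tf$sst_angle_R, 30, tolerance = 0.1)
  expect_equal(tf$sst_angle_sd_L, 0, tolerance = 0.05)
  expect_gt(tf$sst_pct_raised_L, 0)
})

test_that("per-repetition aggregates match their hand-computed values", {
  sim <- sim_protocol(seed = 5, jitter = 0.03)
  tf <- compute_trial_features(sim$recording)
  # recompute the FNT aggregates from the per-rep table by hand
  segs <- segment_recording(sim$recording)
  names(segs) <- vapply(segs, `[[`, character(1), "maneuver")
  arows <- motorkin:::fnt_active_rows(sim$recording, segs$FNT)
  sub <- maneuver_segment("FNT", arows[1] - 1L, arows[length(arows)])
  hand <- motorkin:::smoothed_track(sim$recording, "HAND_L", arows)
  headm <- motorkin:::smoothed_track(sim$recording, "HEAD", arows)
  nose <- headm + matrix(c(0, 0, -0.10), length(arows), 3, byrow = TRUE)
  d <- sqrt(rowSums((hand - nose)^2))
  sub <- split_repetitions(sub, sim$recording, d, 5, side = "L")
  f <- fnt_features(sub, sim$recording, "L")
  expect_equal(f$acc, mean(f$per_rep$min_dist), tolerance = 1e-12)
  expect_equal(f$acc_sd, sd(f$per_rep$min_dist), tolerance = 1e-12)
  expect_equal(f$acc, tf$fnt_acc_L, tolerance = 1e-9)
})

test_that("balance features: programmed hold, offset and null cases", {
  sim <- sim_protocol(seed = 3)
  tf <- compute_trial_features(sim$recording)
  expect_equal(tf$t45_air_L, 10, tolerance = 2 / 30)
  expect_equal(tf$t45_air_R, 10, tolerance = 2 / 30)
  expect_lt(tf$t45_holderr_L, 0.1)
  # hold programmed at 40 deg but evaluated against 45: error 5 deg
  sc <- update_script(motion_script(), t45_angle = 40, fnt_jitter_sd = 0)
  sim40 <- simulate_recording(test_profile(), sc, noiseless_sensor(),
                              seed = 6)
  tf40 <- compute_trial_features(sim40$recording, t45_target = 45)
  expect_equal(tf40$t45_holderr_L, 5, tolerance = 0.1)
  # foot never lifted: airborne time zero
  seg <- maneuver_segment("T45", 0, 300)
  expect_warning(f0 <- t45_features(seg, still_recording(10), "L"),
                 "no airborne")
  expect_equal(f0$airborne, 0)
})

test_that("chair-to-stand features match the programmed motion", {
  sim <- sim_protocol(seed = 3)
  tf <- compute_trial_features(sim$recording)
  expect_equal(tf$cst_disp, 0, tolerance = 1e-6)
  expect_equal(tf$cst_tilt, sim$truth$details$CST$trunk_tilt,
               tolerance = 0.2)
  expect_gt(tf$cst_speed, 0)
})

test_that("asymmetry follows the symmetric percent difference", {
  sub <- as.list(setNames(rep(1, length(motorkin:::SUBMEASURE_NAMES)),
                          motorkin:::SUBMEASURE_NAMES))
  a <- asymmetry_features(sub)
  expect_equal(a$asym_ul, 0)
  expect_equal(a$asym_ll, 0)
  # a single pair with L = 2R: 100*|2-1|/1.5 = 66.67
  sub2 <- sub
  sub2$fnt_acc_L <- 2; sub2$fnt_acc_R <- 1
  sub2$fnt_speed_L <- sub2$fnt_speed_R
  a2 <- asymmetry_features(sub2)
  expect_equal(a2$asym_ul, mean(c(200 / 3, 0, 0, 0)), tolerance = 1e-10)
  # pairs {(1,1),(2,4)} -> mean(0, 66.67) = 33.33
  expect_equal(mean(c(motorkin:::symmetric_pct_diff(1, 1),
                      motorkin:::symmetric_pct_diff(2, 4))), 100 / 3,
               tolerance = 1e-10)
  # all pairs invalid -> NaN with warning (one per limb group)
  sub3 <- lapply(sub, function(x) NA_real_)
  w <- capture_warnings(a3 <- asymmetry_features(sub3))
  expect_match(w, "invalid", all = TRUE)
  expect_true(is.nan(a3$asym_ul))
  expect_true(is.nan(a3$asym_ll))
})

test_that("features are invariant under rigid vertical-axis motion", {
  sim <- sim_protocol(seed = 7)
  rec <- sim$recording
  theta <- 25 * pi / 180
  R <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
  shift <- c(0.3, -0.1, 0.4)
  fr <- rec$frames
  for (j in JOINT_NAMES) {
    cols <- paste(j, c("x", "y", "z"), sep = "_")
    m <- as.matrix(fr[, cols]) %*% t(R)
    fr[cols] <- sweep(m, 2, shift, `+`)
  }
  rec2 <- recording(rec$subject_id, rec$series_index, fr)
  tf1 <- compute_trial_features(rec)
  tf2 <- compute_trial_features(rec2)
  skip_cols <- c("subject_id", "series_index", "valid", "cst_tilt")
  for (cn in setdiff(names(tf1), skip_cols))
    expect_equal(tf2[[cn]], tf1[[cn]], tolerance = 1e-4, label = cn)
  # the frontal trunk angle is camera-frame by definition: translation
  # leaves it unchanged, rotation does not have to
  fr3 <- rec$frames
  for (j in JOINT_NAMES) {
    cols <- paste(j, c("x", "y", "z"), sep = "_")
    fr3[cols] <- sweep(as.matrix(rec$frames[, cols]), 2, shift, `+`)
  }
  tf3 <- compute_trial_features(recording(rec$subject_id, 1, fr3))
  expect_equal(tf3$cst_tilt, tf1$cst_tilt, tolerance = 1e-6)
})

test_that("noisy cohort features stay finite and in range", {
  for (seed in c(21, 22)) {
    sim <- sim_protocol(seed = seed, noisy = TRUE)
    tf <- compute_trial_features(sim$recording)
    expect_true(tf$valid)
    vals <- unlist(tf[motorkin:::SUBMEASURE_NAMES])
    expect_true(all(is.finite(vals)))
    expect_true(tf$sst_angle_L >= 0 && tf$sst_angle_L <= 90)
    expect_true(tf$sst_pct_raised_L >= 0 && tf$sst_pct_raised_L <= 100)
    expect_true(tf$t45_air_L >= 0)
  }
})
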