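test_that("identical seeds give identical recordings", {
  p <- test_profile()
  a <- simulate_recording(p, motion_script(), sensor_model(), seed = 11)
  b <- simulate_recording(p, motion_script(), sensor_model(), seed = 11)
  expect_identical(a$recording$frames, b$recording$frames)
  c <- simulate_recording(p, motion_script(), sensor_model(), seed = 12)
  expect_false(identical(a$recording$frames, c$recording$frames))
})

test_that("ground truth spans are ordered, disjoint and cover the protocol", {
  sim <- sim_protocol()
  man <- sim$truth$maneuvers
  expect_equal(man$maneuver, c("RT", "TT", "FNT", "SST", "T45", "CST"))
  expect_equal(length(sim$truth$greeting_onsets), 6)
  expect_true(all(diff(man$window_start) > 0))
  expect_true(all(man$window_end > man$window_start))
  expect_true(all(man$window_start[-1] >= head(man$window_end, -1) - 1))
  expect_true(all(man$active_start >= man$window_start))
  expect_true(all(man$active_end <= man$window_end))
})

test_that("programmed hold durations land in the ground truth", {
  sim <- sim_protocol()
  d <- sim$truth$details$T45$sides$L
  # programmed airborne time is exactly the scripted 10 s; the apex
  # hold is that minus the transition surplus, so close to 300 frames
  expect_equal(d$airborne, 10)
  expect_lt(abs((d$hold_end - d$hold_start) * sim$truth$rate - 300), 40)
  expect_equal(sim$truth$details$RT$hold, 10)
})

test_that("sensor noise matches the programmed per-axis sigmas", {
  p <- test_profile()
  sc <- update_script(motion_script(), order = "RT", static_hold = 400,
                      rest_gap = 0.2)
  sim <- simulate_recording(p, sc, sensor_model(), seed = 5)
  fr <- sim$recording$frames
  rows <- 2000:(2000 + 9999)   # deep inside the static hold
  s <- sensor_model()$sigma
  expect_equal(sd(fr$HEAD_x[rows]), s["x"], tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(sd(fr$HEAD_y[rows]), s["y"], tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(sd(fr$HEAD_z[rows]), s["z"], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("zeroing the noise gives exact programmed geometry", {
  sim <- sim_protocol(seed = 9)
  fr <- sim$recording$frames
  # at the SST apex the between-leg angle equals the programmed 30 deg
  reps <- sim$truth$details$SST$reps
  apex <- round((reps[[1]]$apex + sim$truth$details$SST$man_start_time * 0) * 30)
  apex_t <- sim$truth$details$SST$man_start_time + reps[[1]]$apex
  i <- which.min(abs(fr$time_s - apex_t))
  hc <- c(fr$HIP_CENTER_x[i], fr$HIP_CENTER_y[i], fr$HIP_CENTER_z[i])
  al <- c(fr$ANKLE_L_x[i], fr$ANKLE_L_y[i], fr$ANKLE_L_z[i])
  ar <- c(fr$ANKLE_R_x[i], fr$ANKLE_R_y[i], fr$ANKLE_R_z[i])
  expect_equal(angle_deg(al - hc, ar - hc), 30, tolerance = 0.01)
})

test_that("simulated feature matrix follows the variance-component model", {
  # same seed -> bitwise identical
  a <- simulate_feature_matrix(10, 3, mu = 5, sigma2_between = 2,
                               sigma2_within = 1, seed = 4)
  b <- simulate_feature_matrix(10, 3, mu = 5, sigma2_between = 2,
                               sigma2_within = 1, seed = 4)
  expect_identical(a, b)
  # degenerate within-variance: identical trials, perfect reliability
  Z <- simulate_feature_matrix(8, 4, mu = 1, sigma2_between = 1,
                               sigma2_within = 0, seed = 2)
  expect_true(all(Z == Z[, 1]))
  expect_equal(icc_oneway(Z)$icc, 1)
  expect_equal(sem_abs(Z), 0)
  # moment recovery at large n
  X <- simulate_feature_matrix(2000, 3, mu = 10, sigma2_between = 4,
                               sigma2_within = 1, seed = 7)
  expect_equal(mean(X), 10, tolerance = 0.05)
  s2w <- sum((X - rowMeans(X))^2) / (2000 * 2)
  s2b <- var(rowMeans(X)) - s2w / 3
  expect_equal(s2w, 1, tolerance = 0.05)
  expect_equal(s2b, 4, tolerance = 0.05 * 4)
  expect_error(simulate_feature_matrix(5, 3, sigma2_between = -1),
               ">= 0")
})

test_that("cohort simulation is seeded and respects script bounds", {
  coh <- simulate_cohort(6, 2, seed = 3)
  coh2 <- simulate_cohort(6, 2, seed = 3)
  expect_identical(coh$subjects, coh2$subjects)
  expect_equal(nrow(coh$subjects), 6)
  expect_setequal(unique(coh$subjects$activity_class),
                  c("active", "sedentary"))
  for (i in 1:6) for (k in 1:2) {
    sc <- coh$scripts[[i]][[k]]
    expect_true(sc$sst_angle_l >= 10 && sc$sst_angle_l <= 80)
    expect_true(sc$fnt_jitter_sd > 0)
  }
})

test_that("script validation rejects out-of-range parameters", {
  expect_error(motion_script(t45_angle = 120), "\\[0, 90\\]")
  expect_error(motion_script(reps = 0), "repetition")
  expect_error(motion_script(static_hold = -1), "positive")
  expect_error(update_script(motion_script(), nonsense = 1), "unknown")
})
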