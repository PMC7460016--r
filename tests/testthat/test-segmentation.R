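test_that("all six greetings are detected near their true onsets", {
  for (noisy in c(FALSE, TRUE)) {
    sim <- sim_protocol(seed = 3, noisy = noisy)
    g <- detect_greetings(sim$recording)
    expect_length(g, 6)
    expect_true(all(diff(g) > 0))
    expect_true(all(abs(g - sim$truth$greeting_onsets) <= 6))  # 0.2 s
  }
})

test_that("a motionless recording yields no greetings", {
  expect_length(detect_greetings(still_recording()), 0)
})

test_that("single-arm oscillation is not a greeting", {
  n <- 360; t <- (0:(n - 1)) / 30
  y0 <- canonical_skeleton(1.70)["WRIST_L", "y"]
  osc <- y0 + 0.35 * 0.5 * (1 - cos(2 * pi * 1.5 * pmax(0, pmin(t - 4, 4 / 3))))
  rec <- still_recording(12, overrides = list(WRIST_L_y = osc))
  expect_length(detect_greetings(rec), 0)
  # the same flap on both wrists IS a greeting
  rec2 <- still_recording(12, overrides = list(WRIST_L_y = osc,
                                               WRIST_R_y = osc))
  g <- detect_greetings(rec2)
  expect_length(g, 1)
  expect_lte(abs(g - 120), 6)
})

test_that("windows line up with ground truth within 0.2 s", {
  sim <- sim_protocol(seed = 3, noisy = TRUE)
  g <- detect_greetings(sim$recording)
  segs <- segment_protocol(sim$recording, g)
  man <- sim$truth$maneuvers
  for (i in seq_along(segs)) {
    expect_equal(segs[[i]]$maneuver, man$maneuver[i])
    expect_lte(abs(segs[[i]]$start - man$window_start[i]), 6)
    expect_lte(abs(segs[[i]]$end - man$window_end[i]), 6)
  }
})

test_that("greeting count mismatches are explicit errors", {
  sim <- sim_protocol()
  expect_error(segment_protocol(sim$recording, c(10L, 500L)),
               "expected 6 greetings, found 2")
  expect_equal(segment_protocol(sim$recording, integer(0),
                                order = character(0)), list())
})

test_that("segmentation is invariant to time translation", {
  sim <- sim_protocol(seed = 4, noisy = TRUE)
  rec <- sim$recording
  shifted <- rec
  shifted$frames$time_s <- shifted$frames$time_s + 1000
  expect_identical(detect_greetings(rec), detect_greetings(shifted))
})

test_that("repetition splitting recovers programmed FNT reps", {
  sim <- sim_protocol(seed = 3)
  segs <- segment_recording(sim$recording)
  names(segs) <- vapply(segs, `[[`, character(1), "maneuver")
  tf <- compute_trial_features(sim$recording)
  expect_true(tf$valid)
  # apices: compare detected CST rep apices against programmed ones
  rows <- (segs$CST$start + 1):segs$CST$end
  hipy <- joint_track(sim$recording, "HIP_CENTER")[rows, "y"]
  sub <- split_repetitions(segs$CST, sim$recording, hipy, 5)
  reps <- sub$repetitions
  expect_equal(nrow(reps), 5)
  d <- sim$truth$details$CST
  prog_apex <- round((d$man_start_time +
                        vapply(d$reps, `[[`, numeric(1), "apex")) * 30)
  expect_true(all(abs(sort(reps$apex) - sort(prog_apex)) <= 15))
})

test_that("flat signals raise a repetition-count error", {
  sim <- sim_protocol(seed = 3)
  segs <- segment_recording(sim$recording)
  names(segs) <- vapply(segs, `[[`, character(1), "maneuver")
  n <- segs$CST$end - segs$CST$start
  expect_error(split_repetitions(segs$CST, sim$recording, rep(1, n), 5),
               "expected 5, found 0")
})

test_that("repetition sub-spans respect segment invariants", {
  seg <- maneuver_segment("FNT", 0, 100)
  reps <- data.frame(side = "L", start = c(10, 40), end = c(30, 60),
                     apex = c(20, 50))
  s2 <- maneuver_segment("FNT", 0, 100, repetitions = reps)
  expect_equal(nrow(s2$repetitions), 2)
  bad <- data.frame(side = "L", start = c(10, 20), end = c(30, 60),
                    apex = c(20, 50))
  expect_error(maneuver_segment("FNT", 0, 100, repetitions = bad),
               "disjoint")
  expect_error(maneuver_segment("FNT", 0, 100,
                                repetitions = data.frame(side = "L",
                                                         start = 90,
                                                         end = 120,
                                                         apex = 95)),
               "contained")
  expect_error(maneuver_segment("RT", 5, 5), "non-empty")
})
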