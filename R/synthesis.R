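# Synthetic skeleton motion generator.
#
# Produces recordings of the six-maneuver protocol from smooth kinematic
# templates: minimum-jerk point-to-point transitions for reaches, steps
# and sit-to-stand, and a raised-cosine oscillation for the greeting
# flap. Every programmed quantity (apex angles, hold times, endpoint
# misses, trunk tilt) is stored in a ground-truth object so downstream
# segmentation and feature extraction can be checked against exact
# values. Sensor noise is i.i.d. Gaussian per joint, frame and axis.

# Run expr with a private RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Canonical standing skeleton for a subject
#'
#' Rest pose of the 20-joint skeleton for a subject of the given stature,
#' standing facing the camera. Camera space: origin at the sensor, +y up,
#' +z from camera toward subject. Segment placements use standard
#' stature-fraction anthropometry; all joints except the feet lie in the
#' frontal plane z = `distance`, which makes frontal-plane rotations of
#' limb chains exact in the programmed angles.
#'
#' @param stature_m subject stature in meters.
#' @param distance camera-to-subject distance in meters.
#' @param sensor_height sensor height above the floor in meters.
#' @return 20 x 3 numeric matrix, rows named by [JOINT_NAMES],
#'   columns x, y, z.
#' @export
canonical_skeleton <- function(stature_m = 1.70, distance = 2.0,
                               sensor_height = 1.0) {
  H <- stature_m
  # (x fraction for the LEFT side at +x, height-above-floor fraction)
  spec <- list(
    HIP_CENTER      = c(0,      0.530),
    SPINE           = c(0,      0.650),
    SHOULDER_CENTER = c(0,      0.820),
    HEAD            = c(0,      0.930),
    SHOULDER        = c(0.130,  0.820),
    ELBOW           = c(0.135,  0.680),
    WRIST           = c(0.135,  0.560),
    HAND            = c(0.135,  0.510),
    HIP             = c(0.060,  0.520),
    KNEE            = c(0.060,  0.285),
    ANKLE           = c(0.060,  0.045),
    FOOT            = c(0.060,  0.020))
  P <- matrix(0, nrow = 20, ncol = 3,
              dimnames = list(JOINT_NAMES, c("x", "y", "z")))
  for (j in JOINT_NAMES) {
    base <- sub("_[LR]$", "", j)
    side <- if (grepl("_L$", j)) 1 else if (grepl("_R$", j)) -1 else 0
    s <- spec[[base]]
    P[j, ] <- c(side * s[1] * H, s[2] * H - sensor_height, distance)
  }
  P["FOOT_L", "z"] <- distance - 0.05
  P["FOOT_R", "z"] <- distance - 0.05
  P
}

# --- pose primitives -------------------------------------------------------

arm_joints <- function(side) paste0(c("SHOULDER_", "ELBOW_", "WRIST_", "HAND_"), side)
leg_joints <- function(side) paste0(c("KNEE_", "ANKLE_", "FOOT_"), side)

# T-position target pose: arms outstretched horizontally at shoulder level.
t_pose <- function(P0, H) {
  P <- P0
  for (side in c("L", "R")) {
    sgn <- if (side == "L") 1 else -1
    sh <- P0[paste0("SHOULDER_", side), ]
    P[paste0("ELBOW_", side), ] <- sh + c(sgn * 0.14 * H, 0, 0)
    P[paste0("WRIST_", side), ] <- sh + c(sgn * 0.26 * H, 0, 0)
    P[paste0("HAND_", side), ]  <- sh + c(sgn * 0.31 * H, 0, 0)
  }
  P
}

# Rotate one leg chain (knee, ankle, foot) about HIP_CENTER in the
# frontal (x-y) plane by delta degrees of abduction (away from midline).
rotate_leg <- function(P, side, delta_deg) {
  sgn <- if (side == "L") 1 else -1
  hc <- P["HIP_CENTER", ]
  for (j in leg_joints(side)) {
    v <- P[j, ] - hc
    r <- sqrt(v[1]^2 + v[2]^2)
    alpha <- atan2(v[1], -v[2])                 # from straight down, toward +x
    alpha2 <- alpha + sgn * delta_deg * pi / 180
    P[j, ] <- hc + c(r * sin(alpha2), -r * cos(alpha2), v[3])
  }
  P
}

# Between-leg angle (deg) of the rest pose: hip-center -> each ankle.
rest_leg_angle <- function(P0) {
  hc <- P0["HIP_CENTER", ]
  angle_deg(P0["ANKLE_L", ] - hc, P0["ANKLE_R", ] - hc)
}

# Forward-facing unit vector of a pose (from the subject toward the
# camera), horizontal; derived from the shoulder line so it follows the
# body under rotations about the vertical axis.
facing_vector <- function(P) {
  sh <- P["SHOULDER_L", ] - P["SHOULDER_R", ]
  f <- c(sh[3] * 1, 0, -sh[1])   # cross(shoulder_line, +y), horizontal
  n <- sqrt(sum(f^2))
  if (n == 0) return(c(0, 0, -1))
  f <- f / n
  if (f[3] > 0) f <- -f          # toward the camera (-z) for a facing subject
  f
}

# Nose landmark proxy: the HEAD joint displaced along the facing
# direction (toward the camera for a subject facing it).
nose_proxy <- function(P, offset = 0.10) {
  P["HEAD", ] + facing_vector(P) * offset
}

# --- timeline assembly -----------------------------------------------------

# A timeline is a list of stages: list(duration, pose(tloc) -> 20x3).
# Arguments are forced: stages are built inside loops and must capture
# the iteration's values, not lazy promises resolved after the loop.
stage <- function(duration, pose) {
  force(duration); force(pose)
  list(duration = duration, pose = pose)
}
static_stage <- function(duration, P) {
  force(P)
  stage(duration, function(t) P)
}

# Greeting: simultaneous bilateral vertical wrist/hand oscillation,
# raised-cosine profile, n full cycles.
greeting_stage <- function(P0, amplitude, freq, cycles) {
  dur <- cycles / freq
  stage(dur, function(t) {
    dy <- amplitude * 0.5 * (1 - cos(2 * pi * freq * t))
    P <- P0
    for (j in c("WRIST_L", "WRIST_R", "HAND_L", "HAND_R"))
      P[j, "y"] <- P[j, "y"] + dy
    for (j in c("ELBOW_L", "ELBOW_R"))
      P[j, "y"] <- P[j, "y"] + 0.5 * dy
    P
  })
}

# Minimum-jerk interpolation between two full poses.
blend_stage <- function(duration, Pa, Pb) {
  force(Pa); force(Pb); force(duration)
  stage(duration, function(t) {
    s <- min_jerk(t / duration)
    Pa + s * (Pb - Pa)
  })
}

# Evaluate a timeline at a fixed frame rate. Returns the frames
# data.frame plus the start time of every stage.
render_timeline <- function(stages, rate) {
  durs <- vapply(stages, `[[`, numeric(1), "duration")
  starts <- cumsum(c(0, durs))
  total <- starts[length(starts)]
  times <- seq(0, total - 1e-9, by = 1 / rate)
  idx <- findInterval(times, starts, rightmost.closed = FALSE)
  idx[idx > length(stages)] <- length(stages)
  mats <- lapply(seq_along(times), function(i) {
    st <- stages[[idx[i]]]
    p <- st$pose(times[i] - starts[idx[i]])
    as.vector(t(p))   # row-major: joint-by-joint x,y,z
  })
  body <- do.call(rbind, mats)
  colnames(body) <- joint_columns()
  frames <- data.frame(frame = seq_along(times) - 1L, time_s = times)
  frames <- cbind(frames, as.data.frame(body))
  list(frames = frames, stage_starts = starts[-length(starts)],
       stage_ends = starts[-1], total = total)
}

time_to_frame <- function(t, rate) as.integer(ceiling(t * rate - 1e-9))

# --- maneuver builders -----------------------------------------------------
# Each builder returns list(stages, active = c(t0, t1) relative to the
# maneuver start, detail = programmed values / repetition spans in
# maneuver-local time).

build_rt <- function(P0, sc) {
  list(stages = list(static_stage(sc$static_hold, P0)),
       active = c(0, sc$static_hold),
       detail = list(hold = sc$static_hold))
}

build_tt <- function(P0, H, sc, trans = 1.0) {
  PT <- t_pose(P0, H)
  list(stages = list(blend_stage(trans, P0, PT),
                     static_stage(sc$static_hold, PT),
                     blend_stage(trans, PT, P0)),
       active = c(trans, trans + sc$static_hold),
       detail = list(hold = sc$static_hold, transition = trans))
}

# Pose of one arm partway (fraction s in [0,1]) from the T position to a
# reach target near the nose; the other joints stay in the T pose.
fnt_arm_pose <- function(PT, side, target, s) {
  hand <- paste0("HAND_", side); wrist <- paste0("WRIST_", side)
  elbow <- paste0("ELBOW_", side)
  sh <- PT[paste0("SHOULDER_", side), ]
  P <- PT
  P[hand, ]  <- PT[hand, ]  + s * (target - PT[hand, ])
  P[wrist, ] <- PT[wrist, ] + s * ((target - facing_vector(PT) * 0.06) - PT[wrist, ])
  P[elbow, ] <- PT[elbow, ] + s * (((sh + target) / 2 - c(0, 0.05, 0)) - PT[elbow, ])
  P
}

fnt_reach_stage <- function(PT, side, target, dur, direction) {
  force(PT); force(side); force(target); force(dur); force(direction)
  stage(dur, function(tt) {
    s <- min_jerk(tt / dur)
    if (direction < 0) s <- 1 - s
    fnt_arm_pose(PT, side, target, s)
  })
}

build_fnt <- function(P0, H, sc, jitter, trans = 1.0, touch = 0.1,
                      pause = 0.3, settle = 0.6) {
  PT <- t_pose(P0, H)
  nose <- nose_proxy(PT)
  # settle pauses at the T position bracket the repetitions so the
  # reach-distance signal has a clean baseline for repetition splitting
  stages <- list(blend_stage(trans, P0, PT), static_stage(settle, PT))
  t <- trans + settle
  reps <- list()
  speeds <- list()
  k <- 0
  for (side in c("L", "R")) {
    reach_len <- sqrt(sum((nose - PT[paste0("HAND_", side), ])^2))
    for (r in seq_len(sc$reps)) {
      k <- k + 1
      target <- nose + jitter[[k]]
      rep_start <- t
      stages <- c(stages, list(
        fnt_reach_stage(PT, side, target, sc$fnt_reach_duration, +1),
        static_stage(touch, fnt_arm_pose(PT, side, target, 1)),
        fnt_reach_stage(PT, side, target, sc$fnt_reach_duration, -1),
        static_stage(pause, PT)))
      t <- t + 2 * sc$fnt_reach_duration + touch + pause
      reps[[k]] <- list(side = side, start = rep_start,
                        end = t,
                        apex = rep_start + sc$fnt_reach_duration,
                        miss = sqrt(sum(jitter[[k]]^2)))
      speeds[[k]] <- reach_len / sc$fnt_reach_duration
    }
  }
  stages <- c(stages, list(static_stage(settle, PT),
                           blend_stage(trans, PT, P0)))
  t <- t + settle
  list(stages = stages,
       active = c(trans, t),
       detail = list(reps = reps,
                     programmed_speed = mean(unlist(speeds)),
                     reach_length = sqrt(sum((nose - PT["HAND_L", ])^2)),
                     nose = nose))
}

build_sst <- function(P0, sc, t_out = 1.0, apex_hold = 0.4, pause = 0.4) {
  theta0 <- rest_leg_angle(P0)
  stages <- list()
  t <- 0
  reps <- list()
  k <- 0
  for (side in c("L", "R")) {
    angle <- if (side == "L") sc$sst_angle_l else sc$sst_angle_r
    delta <- max(angle - theta0, 0)
    Papex <- rotate_leg(P0, side, delta)
    rise_ankle <- Papex[paste0("ANKLE_", side), "y"] - P0[paste0("ANKLE_", side), "y"]
    rise_foot  <- Papex[paste0("FOOT_", side), "y"] - P0[paste0("FOOT_", side), "y"]
    for (r in seq_len(sc$reps)) {
      k <- k + 1
      rep_start <- t
      stages <- c(stages, list(blend_stage(t_out, P0, Papex),
                               static_stage(apex_hold, Papex),
                               blend_stage(t_out, Papex, P0),
                               static_stage(pause, P0)))
      t <- t + 2 * t_out + apex_hold + pause
      reps[[k]] <- list(side = side, start = rep_start, end = t,
                        apex = rep_start + t_out + apex_hold / 2,
                        angle = theta0 + delta,
                        foot_rise = rise_foot, ankle_rise = rise_ankle)
    }
  }
  list(stages = stages, active = c(0, t),
       detail = list(reps = reps, rest_angle = theta0,
                     angle_l = max(sc$sst_angle_l, theta0),
                     angle_r = max(sc$sst_angle_r, theta0)))
}

build_t45 <- function(P0, sc, rate, t_trans = 0.8, pause = 0.5,
                      airborne_margin = 0.05) {
  theta0 <- rest_leg_angle(P0)
  stages <- list()
  t <- 0
  detail <- list(rest_angle = theta0, sides = list())
  for (side in c("L", "R")) {
    delta <- max(sc$t45_angle - theta0, 0)
    Papex <- rotate_leg(P0, side, delta)
    foot <- paste0("FOOT_", side)
    hc <- P0["HIP_CENTER", ]
    v <- P0[foot, ] - hc
    r_f <- sqrt(v[1]^2 + v[2]^2)
    alpha_f <- atan2(abs(v[1]), -v[2])
    rise <- function(d) r_f * (cos(alpha_f) - cos(alpha_f + d * pi / 180))
    # calibrate the apex hold so total time with the foot above
    # baseline + margin equals the programmed airborne time; the lift
    # transition interpolates positions, so the foot height is linear
    # in the minimum-jerk profile
    if (rise(delta) > airborne_margin) {
      s_th <- airborne_margin / rise(delta)
      tau_th <- stats::uniroot(function(tau) min_jerk(tau) - s_th,
                               c(0, 1))$root
      surplus <- (1 - tau_th) * t_trans
    } else surplus <- 0
    hold <- max(sc$t45_hold - 2 * surplus, 0.5)
    hold_start <- t + t_trans
    stages <- c(stages, list(blend_stage(t_trans, P0, Papex),
                             static_stage(hold, Papex),
                             blend_stage(t_trans, Papex, P0),
                             static_stage(pause, P0)))
    knee_flex <- angle_deg(
      Papex[paste0("HIP_", side), ] - Papex[paste0("KNEE_", side), ],
      Papex[paste0("ANKLE_", side), ] - Papex[paste0("KNEE_", side), ])
    detail$sides[[side]] <- list(
      side = side, angle = theta0 + delta,
      hold_start = hold_start, hold_end = hold_start + hold,
      airborne = if (surplus > 0) hold + 2 * surplus else hold,
      foot_rise = rise(delta), knee_flexion = knee_flex,
      start = t, end = t + 2 * t_trans + hold + pause)
    t <- t + 2 * t_trans + hold + pause
  }
  list(stages = stages, active = c(0, t), detail = detail)
}

build_cst <- function(P0, sc, t_down = 1.2, seat_hold = 0.8, t_up = 1.2,
                      pause = 0.6, sensor_height = 1.0) {
  upper <- c("HIP_CENTER", "HIP_L", "HIP_R", "SPINE", "SHOULDER_CENTER",
             "HEAD", "SHOULDER_L", "SHOULDER_R", "ELBOW_L", "ELBOW_R",
             "WRIST_L", "WRIST_R", "HAND_L", "HAND_R")
  trunk <- c("SPINE", "SHOULDER_CENTER", "HEAD", "SHOULDER_L", "SHOULDER_R",
             "ELBOW_L", "ELBOW_R", "WRIST_L", "WRIST_R", "HAND_L", "HAND_R")
  seat_y <- if (is.na(sc$cst_seat_height)) P0["KNEE_L", "y"]
            else sc$cst_seat_height - sensor_height
  drop <- P0["HIP_CENTER", "y"] - seat_y
  if (drop <= 0) stop("seat height must be below standing hip height")
  phi <- sc$cst_trunk_tilt * pi / 180
  seated_pose <- function(s) {
    P <- P0
    P[upper, "y"] <- P[upper, "y"] - s * drop
    hc <- P["HIP_CENTER", ]
    a <- s * phi
    for (j in trunk) {
      v <- P[j, ] - hc
      P[j, ] <- hc + c(cos(a) * v[1] - sin(a) * v[2],
                       sin(a) * v[1] + cos(a) * v[2], v[3])
    }
    P
  }
  Pseat <- seated_pose(1)
  stages <- list()
  t <- 0
  reps <- list()
  for (r in seq_len(sc$reps)) {
    rep_start <- t
    stages <- c(stages, list(
      stage(t_down, function(tt) seated_pose(min_jerk(tt / t_down))),
      static_stage(seat_hold, Pseat),
      stage(t_up, function(tt) seated_pose(1 - min_jerk(tt / t_up))),
      static_stage(pause, P0)))
    t <- t + t_down + seat_hold + t_up + pause
    reps[[r]] <- list(start = rep_start, end = t,
                      apex = rep_start + t_down + seat_hold / 2)
  }
  list(stages = stages, active = c(0, t),
       detail = list(reps = reps, drop = drop,
                     seated_hip = Pseat["HIP_CENTER", ],
                     trunk_tilt = sc$cst_trunk_tilt,
                     mean_hip_speed = 2 * drop / (t_down + t_up)))
}

# --- top-level simulation --------------------------------------------------

#' Simulate one skeleton recording of the six-maneuver protocol
#'
#' Renders a full series — for each maneuver in the scripted order, a
#' greeting flap, a short still pause, the maneuver itself and a rest
#' gap — at the sensor's frame rate, then adds per-axis Gaussian sensor
#' noise. The returned ground truth holds the exact greeting onsets,
#' maneuver windows (greeting end to next greeting start), active spans,
#' repetition spans and every programmed kinematic value, so recovered
#' quantities can be compared against what was programmed.
#'
#' @param profile a [subject_profile()].
#' @param script a [motion_script()].
#' @param sensor a [sensor_model()].
#' @param seed integer seed; sensor noise and reach endpoint jitter are
#'   drawn from substreams derived from it.
#' @param series_index which of the three series this recording is.
#' @param distance camera-to-subject distance, meters.
#' @return list with elements `recording` (a [recording()]) and
#'   `truth` (ground-truth list: `greeting_onsets` in 0-based frames,
#'   `maneuvers` data.frame of half-open `[start, end)` frame spans,
#'   and per-maneuver `details`).
#' @export
simulate_recording <- function(profile, script, sensor = sensor_model(),
                               seed = 1, series_index = 1, distance = 2.0) {
  validate_script(script)
  if (distance < sensor$operating_range[1] ||
      distance > sensor$operating_range[2])
    warning("subject distance ", distance,
            " m is outside the sensor operating range")
  H <- profile$stature_cm / 100
  P0 <- canonical_skeleton(H, distance = distance)
  rate <- sensor$rate
  jseed <- substream_seed(seed, paste0("jitter/", profile$subject_id, "/",
                                       series_index))
  nseed <- substream_seed(seed, paste0("noise/", profile$subject_id, "/",
                                       series_index))
  n_jit <- 2L * script$reps
  jitter <- with_seed(jseed, lapply(seq_len(n_jit), function(i)
    stats::rnorm(3, 0, script$fnt_jitter_sd)))

  stages <- list()
  marks <- list()   # per maneuver: times of greeting onset/end, window, active
  t <- 0
  greet_dur <- script$greeting_cycles / script$greeting_freq
  for (m in script$order) {
    g_on <- t
    stages <- c(stages, list(greeting_stage(P0, script$greeting_amplitude,
                                            script$greeting_freq,
                                            script$greeting_cycles)))
    t <- t + greet_dur
    g_end <- t
    stages <- c(stages, list(static_stage(script$pre_gap, P0)))
    t <- t + script$pre_gap
    b <- switch(m,
      RT  = build_rt(P0, script),
      TT  = build_tt(P0, H, script),
      FNT = build_fnt(P0, H, script, jitter),
      SST = build_sst(P0, script),
      T45 = build_t45(P0, script, rate),
      CST = build_cst(P0, script))
    stages <- c(stages, b$stages)
    m_start <- t
    t <- t + sum(vapply(b$stages, `[[`, numeric(1), "duration"))
    stages <- c(stages, list(static_stage(script$rest_gap, P0)))
    t <- t + script$rest_gap
    marks[[length(marks) + 1]] <- list(
      maneuver = m, greet_on = g_on, greet_end = g_end,
      active = m_start + b$active, man_start = m_start, man_end = t,
      detail = b$detail)
  }
  rt <- render_timeline(stages, rate)
  frames <- rt$frames
  coord_cols <- joint_columns()
  if (any(sensor$sigma > 0)) {
    nfr <- nrow(frames)
    noise <- with_seed(nseed, {
      e <- matrix(stats::rnorm(nfr * 60), nfr, 60)
      sweep(e, 2, rep(sensor$sigma, 20), `*`)  # columns are J_x, J_y, J_z, ...
    })
    frames[coord_cols] <- frames[coord_cols] + noise
  }
  rec <- recording(profile$subject_id, series_index, frames,
                   nominal_rate = rate)

  total_end <- time_to_frame(rt$total, rate)
  n_man <- length(marks)
  truth_man <- do.call(rbind, lapply(seq_len(n_man), function(i) {
    mk <- marks[[i]]
    win_end <- if (i < n_man) marks[[i + 1]]$greet_on else rt$total
    data.frame(maneuver = mk$maneuver,
               greet_onset = time_to_frame(mk$greet_on, rate),
               window_start = time_to_frame(mk$greet_end, rate),
               window_end = min(time_to_frame(win_end, rate), total_end),
               active_start = time_to_frame(mk$active[1], rate),
               active_end = time_to_frame(mk$active[2], rate),
               stringsAsFactors = FALSE)
  }))
  details <- stats::setNames(lapply(marks, function(mk) {
    d <- mk$detail
    d$window_start_time <- mk$greet_end
    d$man_start_time <- mk$man_start
    d
  }), vapply(marks, `[[`, character(1), "maneuver"))
  list(recording = rec,
       truth = list(greeting_onsets = truth_man$greet_onset,
                    maneuvers = truth_man,
                    details = details,
                    rate = rate))
}

#' Simulate a reliability-study cohort
#'
#' Draws subject demographics matching a young adult cohort (age about
#' 24 +/- 5 years, stature 171 +/- 9 cm, mass 73 +/- 13 kg, roughly
#' 60/40 male/female, half active and half sedentary) and, for each
#' subject, individual programmed kinematics: subject-level random
#' effects on step/abduction angles, reach timing, endpoint accuracy and
#' trunk tilt, plus smaller trial-level perturbations per series. These
#' two variance sources are what the downstream ICC/SEM estimates
#' measure.
#'
#' @param n_subjects number of subjects.
#' @param n_series series (trials) per subject, default 3.
#' @param base_script baseline [motion_script()].
#' @param seed master seed.
#' @param subject_sd,trial_sd named lists overriding the default
#'   between-subject / between-trial SDs of the varied script fields
#'   (`sst_angle_l`, `sst_angle_r`, `t45_angle`, `cst_trunk_tilt` in
#'   degrees; `fnt_reach_duration` in s; `fnt_jitter_sd` in m).
#' @return list with `subjects` (data.frame) and `scripts` (list indexed
#'   `[[subject]][[series]]` of per-trial scripts).
#' @export
simulate_cohort <- function(n_subjects, n_series = 3,
                            base_script = motion_script(), seed = 1,
                            subject_sd = list(), trial_sd = list()) {
  s_sd <- utils::modifyList(list(sst_angle_l = 3, sst_angle_r = 3,
                                 t45_angle = 2.5, cst_trunk_tilt = 2,
                                 fnt_reach_duration = 0.12,
                                 fnt_jitter_sd = 0.008), subject_sd)
  t_sd <- utils::modifyList(list(sst_angle_l = 1.5, sst_angle_r = 1.5,
                                 t45_angle = 1.5, cst_trunk_tilt = 1,
                                 fnt_reach_duration = 0.06,
                                 fnt_jitter_sd = 0.003), trial_sd)
  subs <- with_seed(substream_seed(seed, "cohort"), {
    ids <- sprintf("S%03d", seq_len(n_subjects))
    sex <- sample(c("M", "F"), n_subjects, replace = TRUE, prob = c(0.62, 0.38))
    act <- rep(c("active", "sedentary"), length.out = n_subjects)
    lapply(seq_len(n_subjects), function(i) subject_profile(
      ids[i],
      age = max(18, round(stats::rnorm(1, 24, 5))),
      sex = sex[i],
      stature_cm = stats::rnorm(1, 170.7, 9.2),
      mass_kg = max(45, stats::rnorm(1, 72.9, 12.7)),
      activity_min_week = if (act[i] == "active")
        round(stats::runif(1, 150, 600)) else round(stats::runif(1, 0, 149))))
  })
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  vary <- names(s_sd)
  scripts <- lapply(seq_len(n_subjects), function(i) {
    p <- subs[[i]]
    sdev <- with_seed(substream_seed(seed, paste0("subject_fx/", p$subject_id)),
                      stats::setNames(lapply(vary, function(v)
                        stats::rnorm(1, 0, s_sd[[v]])), vary))
    lapply(seq_len(n_series), function(k) {
      tdev <- with_seed(substream_seed(seed, paste0("trial_fx/", p$subject_id,
                                                    "/", k)),
                        stats::setNames(lapply(vary, function(v)
                          stats::rnorm(1, 0, t_sd[[v]])), vary))
      sc <- base_script
      for (v in vary) sc[[v]] <- sc[[v]] + sdev[[v]] + tdev[[v]]
      sc$sst_angle_l <- clamp(sc$sst_angle_l, 10, 80)
      sc$sst_angle_r <- clamp(sc$sst_angle_r, 10, 80)
      sc$t45_angle <- clamp(sc$t45_angle, 15, 80)
      sc$cst_trunk_tilt <- clamp(sc$cst_trunk_tilt, 0.5, 30)
      sc$fnt_reach_duration <- clamp(sc$fnt_reach_duration, 0.4, 3)
      sc$fnt_jitter_sd <- clamp(sc$fnt_jitter_sd, 0.001, 0.2)
      validate_script(sc)
      sc
    })
  })
  list(subjects = subjects_table(subs), profiles = subs, scripts = scripts)
}

#' Simulate a feature matrix with known variance components
#'
#' Generates `y_ij = mu + b_i + e_ij` with subject effects
#' `b_i ~ N(0, sigma2_between)` and trial errors
#' `e_ij ~ N(0, sigma2_within)`: the one-way random-effects model whose
#' population intraclass correlation is
#' `sigma2_between / (sigma2_between + sigma2_within)` and whose
#' within-subject SD is what SEM estimates. This is the ground-truth
#' oracle for the reliability statistics.
#'
#' @param n_subjects rows (subjects), >= 2.
#' @param k_trials columns (trials), >= 2.
#' @param mu trait mean.
#' @param sigma2_between between-subject variance, >= 0.
#' @param sigma2_within within-subject variance, >= 0.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return numeric `n_subjects x k_trials` matrix.
#' @export
simulate_feature_matrix <- function(n_subjects, k_trials, mu = 0,
                                    sigma2_between = 1, sigma2_within = 1,
                                    seed = 1) {
  stopifnot(n_subjects >= 2, k_trials >= 2)
  if (sigma2_between < 0 || sigma2_within < 0)
    stop("variance components must be >= 0")
  with_seed(seed, {
    b <- stats::rnorm(n_subjects, 0, sqrt(sigma2_between))
    e <- matrix(stats::rnorm(n_subjects * k_trials, 0, sqrt(sigma2_within)),
                n_subjects, k_trials)
    mu + b + e
  })
}
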