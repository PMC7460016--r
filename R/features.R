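# Kinematic feature extraction: primary measures (joint distances,
# angles, angular velocities) and the per-maneuver motor variables.
#
# Conventions: positions are smoothed with a 5-frame moving average
# before differentiation (sensor noise at 30 Hz would otherwise dominate
# velocities); angles are in degrees; the "nose" landmark is the HEAD
# joint displaced 0.10 m along the subject's facing direction (derived
# from the shoulder line, so it is invariant under rotations about the
# vertical axis); static holds are trimmed to the central 80% of their
# window to drop transition frames.

seg_rows <- function(rec, seg) {
  lo <- max(seg$start, 0) + 1L
  hi <- min(seg$end, n_frames(rec))
  lo:hi
}

rep_rows <- function(rep_start, rep_end, rec) {
  (max(rep_start, 0) + 1L):min(rep_end, n_frames(rec))
}

# Central fraction of a row span (trim static segments' transitions).
central_rows <- function(rows, frac = 0.8) {
  n <- length(rows)
  drop <- floor(n * (1 - frac) / 2)
  rows[(drop + 1):(n - drop)]
}

smoothed_track <- function(rec, joint, rows = NULL, width = 5) {
  m <- joint_track(rec, joint)
  m <- apply(m, 2, moving_average, width = width)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

#' Primary kinematic measures over a segment
#'
#' Per-frame Euclidean distances between joint pairs, angles at joint
#' triplets (vertex at the middle joint, via the arc cosine of the
#' normalized dot product) and angular velocities of those angles by
#' central differences over the actual inter-frame intervals.
#'
#' @param seg a [maneuver_segment()].
#' @param rec the parent [recording()].
#' @param pairs list of character length-2 joint name vectors.
#' @param triplets list of character length-3 joint name vectors.
#' @param smooth_width moving-average width in frames (1 = off).
#' @return list with `time` (s), `distances` (m), `angles` (deg) and
#'   `angular_velocities` (deg/s), the latter two named by triplet.
#' @export
primary_measures <- function(seg, rec, pairs = list(), triplets = list(),
                             smooth_width = 5) {
  rows <- seg_rows(rec, seg)
  tt <- rec$frames$time_s[rows]
  tracks <- new.env()
  gettrk <- function(j) {
    if (is.null(tracks[[j]]))
      tracks[[j]] <- smoothed_track(rec, j, rows, smooth_width)
    tracks[[j]]
  }
  dists <- lapply(pairs, function(p)
    sqrt(rowSums((gettrk(p[1]) - gettrk(p[2]))^2)))
  names(dists) <- vapply(pairs, paste, character(1), collapse = "-")
  angs <- lapply(triplets, function(tr) {
    v1 <- gettrk(tr[1]) - gettrk(tr[2])
    v2 <- gettrk(tr[3]) - gettrk(tr[2])
    a <- angle_deg(v1, v2)
    if (anyNA(a)) warning("degenerate zero-length limb vector; NaN angle")
    a
  })
  names(angs) <- vapply(triplets, paste, character(1), collapse = "-")
  avel <- lapply(angs, central_diff, t = tt)
  list(time = tt, distances = dists, angles = angs,
       angular_velocities = avel)
}

# Diameter of the 3D point cloud of one joint over rows: the maximum
# pairwise distance (meters). Raw (unsmoothed) positions: this measures
# the full excursion including sensor noise, by design.
cloud_diameter <- function(rec, joint, rows) {
  m <- joint_track(rec, joint)[rows, , drop = FALSE]
  max(stats::dist(m))
}

# Mean speed (m/s) of one joint over rows, from smoothed positions.
mean_speed <- function(rec, joint, rows, width = 5) {
  m <- smoothed_track(rec, joint, rows, width)
  tt <- rec$frames$time_s[rows]
  v <- sqrt(central_diff(m[, 1], tt)^2 + central_diff(m[, 2], tt)^2 +
            central_diff(m[, 3], tt)^2)
  mean(v)
}

path_length <- function(m) sum(sqrt(rowSums(diff(m)^2)))

# Longest run of frames with at least one hand near or above shoulder
# height: the arms-outstretched phase of a T-position or FNT window.
elevated_rows <- function(rec, seg, margin = 0.25) {
  rows <- seg_rows(rec, seg)
  hy <- pmax(rec$frames$HAND_L_y[rows], rec$frames$HAND_R_y[rows])
  shy <- (rec$frames$SHOULDER_L_y[rows] + rec$frames$SHOULDER_R_y[rows]) / 2
  runs <- true_runs(hy > shy - margin)
  if (!nrow(runs)) stop("no arms-raised phase found in window")
  main <- runs[which.max(runs[, "end"] - runs[, "start"]), ]
  rows[main["start"]:main["end"]]
}

# Arm tilt below horizontal (degrees >= 0) of the shoulder->hand vector.
arm_drop_deg <- function(shoulder, hand) {
  v <- hand - shoulder
  n <- sqrt(sum(v^2))
  if (n == 0) return(NaN)
  max(0, asin(-v[2] / n) * 180 / pi)
}

#' Finger-to-nose features for one arm
#'
#' For each identified repetition: the minimum hand-to-nose distance
#' (reach accuracy, m), the hand path speed per phase (to the nose and
#' back, m/s), and the arm tilt below horizontal on return to the T
#' position (arm drop, deg). Aggregates over the repetitions give the
#' mean accuracy, its SD, the mean speed, and the drop mean/SD.
#'
#' @param seg an FNT [maneuver_segment()] with repetitions for `side`.
#' @param rec the parent [recording()].
#' @param side `"L"` or `"R"`.
#' @param nose_offset nose proxy offset from the HEAD joint along the
#'   facing direction, meters.
#' @return list with `acc` (m), `acc_sd` (m), `speed` (m/s), `drop`
#'   (deg), `drop_sd` (deg), `per_rep` data.frame.
#' @export
fnt_features <- function(seg, rec, side, nose_offset = 0.10) {
  reps <- seg$repetitions
  reps <- reps[reps$side == side, , drop = FALSE]
  if (is.null(reps) || !nrow(reps))
    stop("no repetitions identified for side ", side)
  hand <- paste0("HAND_", side)
  shj <- paste0("SHOULDER_", side)
  per <- lapply(seq_len(nrow(reps)), function(i) {
    rows <- rep_rows(reps$start[i], reps$end[i], rec)
    hm <- smoothed_track(rec, hand, rows)
    head_m <- smoothed_track(rec, "HEAD", rows)
    shl <- smoothed_track(rec, "SHOULDER_L", rows)
    shr <- smoothed_track(rec, "SHOULDER_R", rows)
    sline <- shl - shr
    fx <- sline[, 3]; fz <- -sline[, 1]
    fn <- sqrt(fx^2 + fz^2)
    flip <- ifelse(fz > 0, -1, 1)
    nose <- head_m + cbind(flip * fx / fn, 0, flip * fz / fn) * nose_offset
    d <- sqrt(rowSums((hm - nose)^2))
    apex <- which.min(d)
    tt <- rec$frames$time_s[rows]
    sp_out <- if (apex > 1)
      path_length(hm[1:apex, , drop = FALSE]) / (tt[apex] - tt[1]) else NA_real_
    sp_back <- if (apex < length(rows))
      path_length(hm[apex:length(rows), , drop = FALSE]) /
        (tt[length(rows)] - tt[apex]) else NA_real_
    drop <- arm_drop_deg(smoothed_track(rec, shj, rows)[length(rows), ],
                         hm[length(rows), ])
    c(min_dist = min(d), speed = mean(c(sp_out, sp_back), na.rm = TRUE),
      drop = drop)
  })
  per <- as.data.frame(do.call(rbind, per))
  list(acc = mean(per$min_dist), acc_sd = stats::sd(per$min_dist),
       speed = mean(per$speed), drop = mean(per$drop),
       drop_sd = stats::sd(per$drop), per_rep = per)
}

#' Static-hold features (resting and T position)
#'
#' For each hand and for the head, over the central 80% of both static
#' windows: the maximum range of movement (diameter of the 3D point
#' cloud, m) and the mean speed (m/s), averaged across the two
#' conditions. These quantify involuntary movement of the hands and
#' axial (head) stability.
#'
#' @param rt_seg,tt_seg RT and TT [maneuver_segment()]s.
#' @param rec the parent [recording()].
#' @param trim central fraction of each window retained.
#' @return list with `inv_range_L/R`, `inv_speed_L/R` (hands) and
#'   `stab_range`, `stab_speed` (head).
#' @export
static_features <- function(rt_seg, tt_seg, rec, trim = 0.8) {
  for (s in list(rt_seg, tt_seg))
    if ((s$end - s$start) * frame_dt(rec) < 2)
      stop("static segment shorter than 2 s")
  rows_rt <- central_rows(seg_rows(rec, rt_seg), trim)
  # the T hold is the arms-raised run within the window (the window also
  # contains the raise/lower transitions and the trailing rest gap)
  rows_tt <- central_rows(elevated_rows(rec, tt_seg), trim)
  both <- function(joint, fun)
    mean(c(fun(rec, joint, rows_rt), fun(rec, joint, rows_tt)))
  list(inv_range_L = both("HAND_L", cloud_diameter),
       inv_speed_L = both("HAND_L", mean_speed),
       inv_range_R = both("HAND_R", cloud_diameter),
       inv_speed_R = both("HAND_R", mean_speed),
       stab_range = both("HEAD", cloud_diameter),
       stab_speed = both("HEAD", mean_speed))
}

# Between-leg angle series (deg): hip-center -> each ankle.
leg_angle_series <- function(rec, rows, width = 5) {
  hc <- smoothed_track(rec, "HIP_CENTER", rows, width)
  al <- smoothed_track(rec, "ANKLE_L", rows, width)
  ar <- smoothed_track(rec, "ANKLE_R", rows, width)
  angle_deg(al - hc, ar - hc)
}

#' Sideways-step features for one leg
#'
#' Per repetition: the apex between-leg angle (maximum of the smoothed
#' hip-center-to-ankle angle, deg) and the lifted foot's height above
#' its pre-maneuver baseline. Aggregates: mean and SD of the apex angle,
#' mean apex foot rise (m) and mean percentage of repetition time with
#' the foot more than 2 cm above baseline.
#'
#' @param seg an SST [maneuver_segment()] with repetitions for `side`.
#' @param rec the parent [recording()].
#' @param side `"L"` or `"R"`.
#' @param raised_margin height above baseline counting as "raised", m.
#' @return list with `angle`, `angle_sd` (deg), `foot_height` (m),
#'   `pct_raised` (%), `per_rep` data.frame.
#' @export
sst_features <- function(seg, rec, side, raised_margin = 0.02) {
  reps <- seg$repetitions
  reps <- reps[reps$side == side, , drop = FALSE]
  if (is.null(reps) || !nrow(reps))
    stop("no repetitions identified for side ", side)
  foot <- paste0("FOOT_", side)
  base_rows <- seg_rows(rec, seg)
  base_rows <- base_rows[seq_len(max(2, round(0.5 / frame_dt(rec))))]
  baseline <- stats::median(joint_track(rec, foot)[base_rows, "y"])
  per <- lapply(seq_len(nrow(reps)), function(i) {
    rows <- rep_rows(reps$start[i], reps$end[i], rec)
    ang <- leg_angle_series(rec, rows)
    fy <- smoothed_track(rec, foot, rows)[, 2]
    c(angle = max(ang),
      foot_height = max(fy) - baseline,
      pct_raised = 100 * mean(fy > baseline + raised_margin))
  })
  per <- as.data.frame(do.call(rbind, per))
  list(angle = mean(per$angle), angle_sd = stats::sd(per$angle),
       foot_height = mean(per$foot_height),
       pct_raised = mean(per$pct_raised), per_rep = per)
}

#' Single-leg balance features for one leg
#'
#' Airborne time is the total time the lifted foot's height exceeds its
#' pre-maneuver baseline by `airborne_margin`. Over the central airborne
#' frames (trimming `settle` seconds at each end to exclude the lift and
#' lower transitions): the mean absolute deviation of the between-leg
#' angle from the target, and the mean knee flexion (hip-knee-ankle
#' angle) of the lifted leg. Head sway (range and mean speed) over the
#' airborne frames quantifies axial balance.
#'
#' @param seg a T45 [maneuver_segment()].
#' @param rec the parent [recording()].
#' @param side `"L"` or `"R"`.
#' @param target_angle programmed abduction angle, deg.
#' @param airborne_margin meters above baseline counting as airborne.
#' @param settle seconds trimmed from each end of the airborne run.
#' @return list with `airborne` (s), `hold_err` (deg), `knee_flex`
#'   (deg), `head_range` (m), `head_speed` (m/s).
#' @export
t45_features <- function(seg, rec, side, target_angle = 45,
                         airborne_margin = 0.05, settle = 0.6) {
  rows <- seg_rows(rec, seg)
  dt <- frame_dt(rec)
  foot <- paste0("FOOT_", side)
  fy <- smoothed_track(rec, foot, rows)[, 2]
  base_rows <- seq_len(max(2, round(0.5 / dt)))
  baseline <- stats::median(fy[base_rows])
  air <- fy > baseline + airborne_margin
  airborne <- sum(air) * dt
  if (!any(air)) {
    warning("no airborne frames for side ", side)
    return(list(airborne = 0, hold_err = NaN, knee_flex = NaN,
                head_range = NaN, head_speed = NaN))
  }
  runs <- true_runs(air)
  main <- runs[which.max(runs[, "end"] - runs[, "start"]), ]
  hold <- main["start"]:main["end"]
  trim_n <- round(settle / dt)
  if (length(hold) > 2 * trim_n + 2)
    hold <- hold[(trim_n + 1):(length(hold) - trim_n)]
  ang <- leg_angle_series(rec, rows[hold])
  hip <- paste0("HIP_", side); knee <- paste0("KNEE_", side)
  ank <- paste0("ANKLE_", side)
  kf <- angle_deg(smoothed_track(rec, hip, rows[hold]) -
                    smoothed_track(rec, knee, rows[hold]),
                  smoothed_track(rec, ank, rows[hold]) -
                    smoothed_track(rec, knee, rows[hold]))
  air_rows <- rows[which(air)]
  list(airborne = airborne,
       hold_err = mean(abs(ang - target_angle)),
       knee_flex = mean(kf),
       head_range = cloud_diameter(rec, "HEAD", air_rows),
       head_speed = mean_speed(rec, "HEAD", air_rows))
}

#' Chair-to-stand features
#'
#' Over the identified sit-stand repetitions: the 3D dispersion (root
#' mean square distance from the centroid) of the pelvis position at the
#' seated extremum across repetitions (m); the mean vertical pelvis
#' speed during the moving phases of descent and ascent (m/s); and the
#' maximum frontal-plane trunk angle, the angle of the
#' shoulder-center-to-pelvis vector from vertical projected on the
#' camera x-y plane (deg; camera-frame definition).
#'
#' @param seg a CST [maneuver_segment()] with repetitions.
#' @param rec the parent [recording()].
#' @param moving_speed vertical speed threshold (m/s) above which the
#'   pelvis counts as moving.
#' @return list with `disp` (m), `hip_speed` (m/s), `trunk_tilt` (deg),
#'   `seated` matrix of per-rep seated pelvis positions.
#' @export
cst_features <- function(seg, rec, moving_speed = 0.05) {
  reps <- seg$repetitions
  if (is.null(reps) || !nrow(reps)) stop("no repetitions identified")
  seated <- matrix(NA_real_, nrow(reps), 3)
  speeds <- numeric(0)
  tilts <- numeric(nrow(reps))
  for (i in seq_len(nrow(reps))) {
    rows <- rep_rows(reps$start[i], reps$end[i], rec)
    hip <- smoothed_track(rec, "HIP_CENTER", rows)
    tt <- rec$frames$time_s[rows]
    seated[i, ] <- hip[which.min(hip[, 2]), ]
    vy <- abs(central_diff(hip[, 2], tt))
    speeds <- c(speeds, vy[vy > moving_speed])
    sc <- smoothed_track(rec, "SHOULDER_CENTER", rows)
    v <- sc - hip
    tilts[i] <- max(atan2(abs(v[, 1]), v[, 2]) * 180 / pi)
  }
  centroid <- colMeans(seated)
  list(disp = sqrt(mean(rowSums(sweep(seated, 2, centroid)^2))),
       hip_speed = if (length(speeds)) mean(speeds) else 0,
       trunk_tilt = max(tilts),
       seated = seated)
}

#' Limb asymmetry from paired left/right sub-measures
#'
#' For each left/right pair, the symmetric percent difference
#' `100 * |L - R| / ((L + R) / 2)` (zero when both sides are zero);
#' the asymmetry index is the mean over the pairs. Upper-limb pairs:
#' reach accuracy, reach speed, reach variability, hand involuntary
#' movement range. Lower-limb pairs: apex foot rise, airborne time,
#' step angle.
#'
#' @param sub named list or one-row data.frame of trial sub-measures
#'   (see [compute_trial_features()]).
#' @return list with `asym_ul` and `asym_ll`, percent.
#' @export
asymmetry_features <- function(sub) {
  pick <- function(nm) as.numeric(sub[[nm]])
  ul_pairs <- list(c("fnt_acc_L", "fnt_acc_R"),
                   c("fnt_speed_L", "fnt_speed_R"),
                   c("fnt_acc_sd_L", "fnt_acc_sd_R"),
                   c("inv_range_L", "inv_range_R"))
  ll_pairs <- list(c("sst_foot_height_L", "sst_foot_height_R"),
                   c("t45_air_L", "t45_air_R"),
                   c("sst_angle_L", "sst_angle_R"))
  asym <- function(pairs) {
    vals <- vapply(pairs, function(p) {
      l <- pick(p[1]); r <- pick(p[2])
      if (!is.finite(l) || !is.finite(r)) return(NA_real_)
      symmetric_pct_diff(l, r)
    }, numeric(1))
    if (all(is.na(vals))) {
      warning("all left/right pairs invalid; asymmetry is NaN")
      return(NaN)
    }
    mean(vals, na.rm = TRUE)
  }
  list(asym_ul = asym(ul_pairs), asym_ll = asym(ll_pairs))
}
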