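# From one segmented recording to the physical sub-measures of a trial,
# and from a cohort of trials to the 20 motor variables.
#
# Several motor variables group more than one physical sub-measure
# (e.g. reach accuracy AND arm drop). Each such variable is reported as
# an equal-weight composite of the sub-measures' z-scores, standardized
# against a reference cohort (by default the input cohort itself); the
# sub-measures are also kept individually, so every number remains
# physically interpretable. Single-measure variables (step amplitude,
# reach speed, seated-position dispersion, the asymmetry indices) are
# reported in their physical units.

SUBMEASURE_NAMES <- c(
  "fnt_acc_L", "fnt_acc_sd_L", "fnt_drop_L", "fnt_drop_sd_L", "fnt_speed_L",
  "fnt_acc_R", "fnt_acc_sd_R", "fnt_drop_R", "fnt_drop_sd_R", "fnt_speed_R",
  "inv_range_L", "inv_speed_L", "inv_range_R", "inv_speed_R",
  "stab_range", "stab_speed",
  "sst_angle_L", "sst_angle_sd_L", "sst_foot_height_L", "sst_pct_raised_L",
  "sst_angle_R", "sst_angle_sd_R", "sst_foot_height_R", "sst_pct_raised_R",
  "t45_air_L", "t45_holderr_L", "t45_knee_L",
  "t45_air_R", "t45_holderr_R", "t45_knee_R",
  "bal_range", "bal_speed",
  "cst_disp", "cst_speed", "cst_tilt")

#' The 20 motor variables
#'
#' Canonical names of the motor variables produced by
#' [feature_matrix()], in reporting order.
#' @format character vector of length 20.
#' @export
MOTOR_VARIABLES <- c(
  "AccMov_LA", "AccMov_RA", "Veloc_LA", "Veloc_RA",
  "VarMov_LA", "VarMov_RA", "InvMov_LA", "InvMov_RA",
  "VarMov_LL", "VarMov_RL", "MonSt_Bal_LL", "MonSt_Bal_RL",
  "AmpStep_LL", "AmpStep_RL", "Var_Mov_axial", "Stab_axial",
  "Asymmetry_UL", "Asymmetry_LL", "Posture_CST", "Bal_axial")

# The FNT reaches happen within the arms-outstretched phase of the
# window (reaches keep the hands near shoulder level).
fnt_active_rows <- function(rec, seg, margin = 0.25) {
  elevated_rows(rec, seg, margin)
}

#' Compute all trial sub-measures from one recording
#'
#' Runs greeting detection, protocol segmentation, repetition splitting
#' and per-maneuver feature extraction, returning one row of physical
#' sub-measures. Maneuvers whose repetitions cannot be identified yield
#' `NA` sub-measures with a warning (the trial is flagged, not fatal).
#'
#' @param rec a [recording()].
#' @param reps expected repetitions per side for FNT/SST/CST.
#' @param order protocol maneuver order.
#' @param t45_target programmed abduction angle for the balance hold,
#'   deg.
#' @param min_amplitude,band greeting detector settings, see
#'   [detect_greetings()].
#' @param segments optional precomputed list of [maneuver_segment()]s
#'   (skips detection).
#' @return one-row data.frame: `subject_id`, `series_index`, the
#'   sub-measures, and `valid` (logical).
#' @export
compute_trial_features <- function(rec, reps = 5,
                                   order = c("RT", "TT", "FNT", "SST",
                                             "T45", "CST"),
                                   t45_target = 45,
                                   min_amplitude = 0.1, band = c(0.5, 3),
                                   segments = NULL) {
  out <- stats::setNames(as.list(rep(NA_real_, length(SUBMEASURE_NAMES))),
                         SUBMEASURE_NAMES)
  valid <- TRUE
  segs <- tryCatch({
    if (is.null(segments))
      segment_recording(rec, min_amplitude, band, order)
    else segments
  }, error = function(e) {
    warning("segmentation failed for ", rec$subject_id, "/",
            rec$series_index, ": ", conditionMessage(e))
    NULL
  })
  if (!is.null(segs)) {
    names(segs) <- vapply(segs, `[[`, character(1), "maneuver")
    # static holds
    if (all(c("RT", "TT") %in% names(segs))) {
      st <- tryCatch(static_features(segs$RT, segs$TT, rec),
                     error = function(e) { warning(conditionMessage(e)); NULL })
      if (!is.null(st)) out[names(st)] <- st else valid <- FALSE
    }
    # finger-to-nose
    if ("FNT" %in% names(segs)) {
      res <- tryCatch({
        seg <- segs$FNT
        arows <- fnt_active_rows(rec, seg)
        sub <- maneuver_segment("FNT", arows[1] - 1L,
                                arows[length(arows)], side = "both")
        for (side in c("L", "R")) {
          hand <- smoothed_track(rec, paste0("HAND_", side), arows)
          headm <- smoothed_track(rec, "HEAD", arows)
          shl <- smoothed_track(rec, "SHOULDER_L", arows)
          shr <- smoothed_track(rec, "SHOULDER_R", arows)
          sline <- shl - shr
          fx <- sline[, 3]; fz <- -sline[, 1]
          fn <- sqrt(fx^2 + fz^2)
          flip <- ifelse(fz > 0, -1, 1)
          nose <- headm + cbind(flip * fx / fn, 0, flip * fz / fn) * 0.10
          d <- sqrt(rowSums((hand - nose)^2))
          sub <- split_repetitions(sub, rec, d, reps, side = side)
        }
        list(L = fnt_features(sub, rec, "L"), R = fnt_features(sub, rec, "R"))
      }, error = function(e) { warning("FNT: ", conditionMessage(e)); NULL })
      if (!is.null(res)) {
        for (side in c("L", "R")) {
          f <- res[[side]]
          out[[paste0("fnt_acc_", side)]] <- f$acc
          out[[paste0("fnt_acc_sd_", side)]] <- f$acc_sd
          out[[paste0("fnt_drop_", side)]] <- f$drop
          out[[paste0("fnt_drop_sd_", side)]] <- f$drop_sd
          out[[paste0("fnt_speed_", side)]] <- f$speed
        }
      } else valid <- FALSE
    }
    # sideways step
    if ("SST" %in% names(segs)) {
      res <- tryCatch({
        seg <- segs$SST
        rows <- seg_rows(rec, seg)
        sub <- seg
        for (side in c("L", "R")) {
          disp <- abs(smoothed_track(rec, paste0("ANKLE_", side), rows)[, 1] -
                        stats::median(joint_track(rec, paste0("ANKLE_", side))[
                          rows[seq_len(min(15, length(rows)))], "x"]))
          sub <- split_repetitions(sub, rec, disp, reps, side = side)
        }
        list(L = sst_features(sub, rec, "L"), R = sst_features(sub, rec, "R"))
      }, error = function(e) { warning("SST: ", conditionMessage(e)); NULL })
      if (!is.null(res)) {
        for (side in c("L", "R")) {
          f <- res[[side]]
          out[[paste0("sst_angle_", side)]] <- f$angle
          out[[paste0("sst_angle_sd_", side)]] <- f$angle_sd
          out[[paste0("sst_foot_height_", side)]] <- f$foot_height
          out[[paste0("sst_pct_raised_", side)]] <- f$pct_raised
        }
      } else valid <- FALSE
    }
    # monopodal balance
    if ("T45" %in% names(segs)) {
      res <- tryCatch(
        list(L = t45_features(segs$T45, rec, "L", t45_target),
             R = t45_features(segs$T45, rec, "R", t45_target)),
        error = function(e) { warning("T45: ", conditionMessage(e)); NULL })
      if (!is.null(res)) {
        for (side in c("L", "R")) {
          f <- res[[side]]
          out[[paste0("t45_air_", side)]] <- f$airborne
          out[[paste0("t45_holderr_", side)]] <- f$hold_err
          out[[paste0("t45_knee_", side)]] <- f$knee_flex
        }
        out$bal_range <- mean(c(res$L$head_range, res$R$head_range))
        out$bal_speed <- mean(c(res$L$head_speed, res$R$head_speed))
      } else valid <- FALSE
    }
    # chair-to-stand
    if ("CST" %in% names(segs)) {
      res <- tryCatch({
        seg <- segs$CST
        rows <- seg_rows(rec, seg)
        hipy <- smoothed_track(rec, "HIP_CENTER", rows)[, 2]
        sub <- split_repetitions(seg, rec, hipy, reps, side = "na")
        cst_features(sub, rec)
      }, error = function(e) { warning("CST: ", conditionMessage(e)); NULL })
      if (!is.null(res)) {
        out$cst_disp <- res$disp
        out$cst_speed <- res$hip_speed
        out$cst_tilt <- res$trunk_tilt
      } else valid <- FALSE
    }
  } else valid <- FALSE
  cbind(data.frame(subject_id = rec$subject_id,
                   series_index = rec$series_index,
                   stringsAsFactors = FALSE),
        as.data.frame(out), valid = valid)
}

# Equal-weight mean of z-scores; reference moments from the reference
# cohort. A zero-variance sub-measure contributes z = 0.
z_composite <- function(df, ref, cols) {
  z <- vapply(cols, function(cn) {
    mu <- mean(ref[[cn]], na.rm = TRUE)
    sdv <- stats::sd(ref[[cn]], na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) rep(0, nrow(df))
    else (df[[cn]] - mu) / sdv
  }, numeric(nrow(df)))
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(df))
  rowMeans(z)
}

#' Assemble the 20 motor variables from trial sub-measures
#'
#' Maps the physical sub-measures of each trial to the 20 motor
#' variables. Multi-measure variables are equal-weight z-score
#' composites standardized against `reference` (default: the input
#' cohort); single-measure variables keep their physical units
#' (degrees for step amplitude, m/s for reach speed, meters for
#' seated-position dispersion, percent for the asymmetry indices).
#'
#' @param sub data.frame of trial rows from [compute_trial_features()].
#' @param reference reference cohort for standardization (same columns).
#' @return long data.frame: `subject_id`, `series_index`, `variable`,
#'   `value`, `valid`.
#' @export
feature_matrix <- function(sub, reference = sub) {
  asym <- lapply(seq_len(nrow(sub)), function(i)
    tryCatch(asymmetry_features(sub[i, ]),
             error = function(e) list(asym_ul = NaN, asym_ll = NaN)))
  vals <- data.frame(
    subject_id = sub$subject_id, series_index = sub$series_index,
    AccMov_LA = z_composite(sub, reference, c("fnt_acc_L", "fnt_drop_L")),
    AccMov_RA = z_composite(sub, reference, c("fnt_acc_R", "fnt_drop_R")),
    Veloc_LA = sub$fnt_speed_L,
    Veloc_RA = sub$fnt_speed_R,
    VarMov_LA = z_composite(sub, reference, c("fnt_acc_sd_L", "fnt_drop_sd_L")),
    VarMov_RA = z_composite(sub, reference, c("fnt_acc_sd_R", "fnt_drop_sd_R")),
    InvMov_LA = z_composite(sub, reference, c("inv_range_L", "inv_speed_L")),
    InvMov_RA = z_composite(sub, reference, c("inv_range_R", "inv_speed_R")),
    VarMov_LL = z_composite(sub, reference,
                            c("sst_foot_height_L", "sst_pct_raised_L",
                              "sst_angle_sd_L")),
    VarMov_RL = z_composite(sub, reference,
                            c("sst_foot_height_R", "sst_pct_raised_R",
                              "sst_angle_sd_R")),
    MonSt_Bal_LL = z_composite(sub, reference,
                               c("t45_air_L", "t45_holderr_L", "t45_knee_L")),
    MonSt_Bal_RL = z_composite(sub, reference,
                               c("t45_air_R", "t45_holderr_R", "t45_knee_R")),
    AmpStep_LL = sub$sst_angle_L,
    AmpStep_RL = sub$sst_angle_R,
    Var_Mov_axial = sub$cst_disp,
    Stab_axial = z_composite(sub, reference, c("stab_range", "stab_speed")),
    Asymmetry_UL = vapply(asym, `[[`, numeric(1), "asym_ul"),
    Asymmetry_LL = vapply(asym, `[[`, numeric(1), "asym_ll"),
    Posture_CST = z_composite(sub, reference, c("cst_speed", "cst_tilt")),
    Bal_axial = z_composite(sub, reference, c("bal_range", "bal_speed")),
    stringsAsFactors = FALSE)
  long <- stats::reshape(
    vals, direction = "long",
    varying = MOTOR_VARIABLES, v.names = "value",
    times = MOTOR_VARIABLES, timevar = "variable",
    idvar = c("subject_id", "series_index"))
  rownames(long) <- NULL
  long$valid <- sub$valid[match(
    paste(long$subject_id, long$series_index),
    paste(sub$subject_id, sub$series_index))] & is.finite(long$value)
  long[order(match(long$variable, MOTOR_VARIABLES), long$subject_id,
             long$series_index),
       c("subject_id", "series_index", "variable", "value", "valid")]
}
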