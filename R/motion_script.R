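#' Maneuver protocol script
#'
#' The programmed kinematics of one pass through the six-maneuver
#' protocol. Each maneuver is preceded by a scripted bilateral arm-flap
#' "greeting" that marks its start for later segmentation. Static holds
#' (resting stance, T position, single-leg balance) last `static_hold` /
#' `t45_hold` seconds; dynamic maneuvers (finger-to-nose, sideways step,
#' chair-to-stand) are repeated `reps` times per side.
#'
#' @param greeting_amplitude peak vertical wrist excursion of the greeting
#'   flap, meters.
#' @param greeting_freq flap frequency, Hz.
#' @param greeting_cycles number of flap cycles.
#' @param static_hold duration of the resting and T-position holds, s.
#' @param fnt_reach_duration duration of each reach phase (to the nose,
#'   and back to the T position), s.
#' @param fnt_jitter_sd SD of the Gaussian endpoint error added to each
#'   nose touch, meters (0 = perfectly accurate reaches).
#' @param sst_angle_l,sst_angle_r programmed between-leg angle at the
#'   apex of left/right sideways steps, degrees.
#' @param t45_angle programmed between-leg abduction angle of the
#'   single-leg balance hold, degrees.
#' @param t45_hold programmed airborne time of the lifted foot, s.
#' @param cst_seat_height seat height above the floor, meters; `NA` means
#'   knee height (hips level with knees when seated).
#' @param cst_trunk_tilt maximum frontal-plane trunk tilt while seated,
#'   degrees.
#' @param reps repetitions for FNT/SST (per side) and CST.
#' @param pre_gap still pause between a greeting and its maneuver, s.
#' @param rest_gap still pause after each maneuver, s.
#' @param order maneuver order; the standard protocol is
#'   RT, TT, FNT, SST, T45, CST.
#' @return object of class `motorkin_script`.
#' @export
motion_script <- function(greeting_amplitude = 0.35,
                          greeting_freq = 1.5,
                          greeting_cycles = 2,
                          static_hold = 10,
                          fnt_reach_duration = 1.0,
                          fnt_jitter_sd = 0.02,
                          sst_angle_l = 30,
                          sst_angle_r = 30,
                          t45_angle = 45,
                          t45_hold = 10,
                          cst_seat_height = NA,
                          cst_trunk_tilt = 8,
                          reps = 5,
                          pre_gap = 0.5,
                          rest_gap = 3,
                          order = c("RT", "TT", "FNT", "SST", "T45", "CST")) {
  sc <- structure(as.list(environment()), class = "motorkin_script")
  validate_script(sc)
  sc
}

#' Validate a motion script
#' @param sc a [motion_script()].
#' @return `sc`, invisibly.
#' @export
validate_script <- function(sc) {
  stopifnot(inherits(sc, "motorkin_script"))
  with(sc, {
    if (any(c(static_hold, t45_hold, fnt_reach_duration,
              greeting_freq, greeting_cycles) <= 0))
      stop("script durations and frequencies must be positive")
    for (a in c(sst_angle_l, sst_angle_r, t45_angle, cst_trunk_tilt))
      if (a < 0 || a > 90) stop("script angles must lie in [0, 90] degrees")
    if (reps < 1) stop("repetition count must be >= 1")
    if (fnt_jitter_sd < 0) stop("fnt_jitter_sd must be >= 0")
    if (greeting_amplitude <= 0) stop("greeting amplitude must be positive")
    bad <- setdiff(order, c("RT", "TT", "FNT", "SST", "T45", "CST"))
    if (length(bad)) stop("unknown maneuver(s) in order: ",
                          paste(bad, collapse = ", "))
  })
  invisible(sc)
}

#' Modify a motion script
#'
#' @param sc a [motion_script()].
#' @param ... named fields to replace.
#' @return the modified, re-validated script.
#' @export
update_script <- function(sc, ...) {
  dots <- list(...)
  bad <- setdiff(names(dots), names(sc))
  if (length(bad)) stop("unknown script field(s): ", paste(bad, collapse = ", "))
  sc[names(dots)] <- dots
  validate_script(sc)
  sc
}
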