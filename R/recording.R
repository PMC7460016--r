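#' Skeleton recording object
#'
#' A recording is one continuous capture of a subject performing the
#' six-maneuver protocol: an ordered sequence of skeleton frames, each
#' holding a timestamp and the 3D camera-space position of all 20 joints.
#' Coordinates are in meters in a right-handed camera frame: origin at the
#' sensor, +y up, +z from the camera toward the subject.
#'
#' @param subject_id character token identifying the subject.
#' @param series_index integer 1..3; which of the three repeated series
#'   this recording belongs to.
#' @param frames data.frame with columns `frame` (0-based index), `time_s`
#'   (seconds from start, strictly increasing) and the 60 coordinate
#'   columns named `<JOINT>_x/_y/_z` for every joint in [JOINT_NAMES].
#' @param nominal_rate nominal sampling rate in Hz (default 30).
#' @return object of class `motorkin_recording`.
#' @export
recording <- function(subject_id, series_index, frames, nominal_rate = 30) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         series_index = as.integer(series_index),
         nominal_rate = as.numeric(nominal_rate),
         frames = frames),
    class = "motorkin_recording")
  validate_recording(rec)
  rec
}

#' Validate a recording's invariants
#'
#' Checks joint completeness, coordinate finiteness and strict time
#' monotonicity; errors name the offending joint or frame.
#'
#' @param rec a [recording()].
#' @return `rec`, invisibly.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "motorkin_recording"))
  if (!rec$series_index %in% 1:3)
    stop("series_index must be 1, 2 or 3, got ", rec$series_index)
  fr <- rec$frames
  if (!is.data.frame(fr) || nrow(fr) < 2L)
    stop("recording must contain at least 2 frames")
  need <- joint_columns()
  missing <- setdiff(need, names(fr))
  if (length(missing)) {
    joints <- unique(sub("_[xyz]$", "", missing))
    stop("recording format error: missing joint column(s) for ",
         paste(joints, collapse = ", "))
  }
  if (!all(c("frame", "time_s") %in% names(fr)))
    stop("recording format error: missing 'frame' or 'time_s' column")
  bad <- which(!is.finite(as.matrix(fr[, need])), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite coordinate at frame index ", fr$frame[bad[1, 1]],
         " (column ", need[bad[1, 2]], ")")
  dt <- diff(fr$time_s)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1]
    stop("frame times not strictly increasing at row ", i + 1L,
         " (frame index ", fr$frame[i + 1L], ")")
  }
  invisible(rec)
}

#' @export
print.motorkin_recording <- function(x, ...) {
  cat(sprintf(
    "<motorkin_recording> subject %s, series %d: %d frames, %.1f s @ %g Hz nominal\n",
    x$subject_id, x$series_index, nrow(x$frames),
    diff(range(x$frames$time_s)), x$nominal_rate))
  invisible(x)
}

#' Number of frames in a recording
#' @param rec a [recording()].
#' @return integer frame count.
#' @export
n_frames <- function(rec) nrow(rec$frames)

#' Median sampling interval of a recording, in seconds
#' @param rec a [recording()].
#' @return numeric scalar.
#' @export
frame_dt <- function(rec) stats::median(diff(rec$frames$time_s))

#' Subject profile
#'
#' Demographics and activity status for one subject. BMI is always derived
#' from mass and stature (never stored independently), and the activity
#' class follows the 150 min/week guideline: subjects reporting at least
#' 150 minutes of weekly physical activity are classed `"active"`,
#' otherwise `"sedentary"`.
#'
#' @param subject_id character token.
#' @param age years.
#' @param sex `"M"` or `"F"`.
#' @param stature_cm stature in centimeters.
#' @param mass_kg body mass in kilograms.
#' @param activity_min_week self-reported weekly physical activity, minutes.
#' @return object of class `motorkin_subject` (a one-row-like list) with
#'   derived fields `bmi` (kg/m^2) and `activity_class`.
#' @export
subject_profile <- function(subject_id, age, sex, stature_cm, mass_kg,
                            activity_min_week) {
  sex <- match.arg(toupper(as.character(sex)), c("M", "F"))
  stopifnot(age > 0, stature_cm > 0, mass_kg > 0, activity_min_week >= 0)
  structure(
    list(subject_id = as.character(subject_id),
         age = as.numeric(age), sex = sex,
         stature_cm = as.numeric(stature_cm),
         mass_kg = as.numeric(mass_kg),
         bmi = as.numeric(mass_kg) / (as.numeric(stature_cm) / 100)^2,
         activity_min_week = as.numeric(activity_min_week),
         activity_class = if (activity_min_week >= 150) "active" else "sedentary"),
    class = "motorkin_subject")
}

#' @export
print.motorkin_subject <- function(x, ...) {
  cat(sprintf("<motorkin_subject> %s: %s, %.0f y, %.0f cm, %.0f kg (BMI %.1f), %s\n",
              x$subject_id, x$sex, x$age, x$stature_cm, x$mass_kg, x$bmi,
              x$activity_class))
  invisible(x)
}

#' Convert subject profiles to a data.frame
#'
#' @param profiles list of [subject_profile()] objects.
#' @return data.frame, one row per subject, BMI and activity class derived.
#' @export
subjects_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, age = p$age, sex = p$sex,
               stature_cm = p$stature_cm, mass_kg = p$mass_kg,
               bmi = p$bmi, activity_min_week = p$activity_min_week,
               activity_class = p$activity_class,
               stringsAsFactors = FALSE)))
}
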