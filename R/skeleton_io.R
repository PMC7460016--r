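#' Read a skeleton recording file
#'
#' The on-disk dialect is a single UTF-8 text file: line 1 is a JSON
#' metadata header prefixed by `#` (subject_id, series_index, nominal_rate
#' and the coordinate convention string), followed by a CSV body with
#' columns `frame`, `time_s` and the 60 joint coordinate columns
#' `<JOINT>_x/_y/_z`. Joints are matched by column name, so any column
#' permutation is read correctly; a missing joint triplet is a format
#' error naming the joint.
#'
#' @param path path to a recording file written by [write_recording()].
#' @return a validated [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(header, "#"))
    stop("recording format error: missing JSON metadata header in ", path)
  meta <- jsonlite::fromJSON(sub("^#", "", header))
  body <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("frame", "time_s", joint_columns())
  missing <- setdiff(need, names(body))
  if (length(missing)) {
    joints <- unique(sub("_[xyz]$", "", setdiff(missing, c("frame", "time_s"))))
    stop("recording format error: missing joint column(s) for ",
         paste(if (length(joints)) joints else missing, collapse = ", "))
  }
  recording(subject_id = meta$subject_id,
            series_index = meta$series_index,
            frames = body[, need],
            nominal_rate = meta$nominal_rate)
}

#' Write a skeleton recording file
#'
#' Serializes a recording in the dialect read by [read_recording()].
#' Coordinates are written with 7 decimal places (0.1 micrometer),
#' well below the depth sensor noise floor, so a read/write round trip
#' is value-exact at that precision.
#'
#' @param rec a validated [recording()].
#' @param path destination path.
#' @param digits decimal places for coordinates and times (minimum 6).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 7) {
  validate_recording(rec)
  if (digits < 6) stop("digits must be >= 6 (sub-millimeter serialization)")
  meta <- list(subject_id = rec$subject_id,
               series_index = rec$series_index,
               nominal_rate = rec$nominal_rate,
               coordinates = "camera-space meters; right-handed; +y up; +z camera->subject; origin at sensor")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  fr <- rec$frames
  num <- setdiff(names(fr), "frame")
  fr[num] <- lapply(fr[num], function(v) formatC(v, digits = digits,
                                                 format = "f"))
  utils::write.table(fr, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' One CSV row per subject with columns `subject_id`, `age`, `sex`,
#' `stature_cm`, `mass_kg`, `activity_min_week`. BMI and activity class
#' are re-derived on read so the stored file can never contradict them.
#'
#' @param path path to a subjects CSV.
#' @return data.frame as from [subjects_table()].
#' @export
read_subjects <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "stature_cm", "mass_kg",
            "activity_min_week")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("subjects file missing column(s): ", paste(missing, collapse = ", "))
  subjects_table(lapply(seq_len(nrow(raw)), function(i)
    subject_profile(raw$subject_id[i], raw$age[i], raw$sex[i],
                    raw$stature_cm[i], raw$mass_kg[i],
                    raw$activity_min_week[i])))
}

#' Write a subject metadata table
#'
#' @param subjects data.frame from [subjects_table()] or a list of
#'   [subject_profile()] objects.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  if (!is.data.frame(subjects)) subjects <- subjects_table(subjects)
  utils::write.csv(subjects[, c("subject_id", "age", "sex", "stature_cm",
                                "mass_kg", "activity_min_week")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
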