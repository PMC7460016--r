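#' The canonical 20-joint markerless skeleton
#'
#' Joint names of the 20-point depth-camera skeleton used throughout the
#' package, in canonical order. All recordings, features and file formats
#' refer to joints by these names, never by column position.
#'
#' @format Character vector of length 20.
#' @export
JOINT_NAMES <- c(
  "HIP_CENTER", "SPINE", "SHOULDER_CENTER", "HEAD",
  "SHOULDER_L", "SHOULDER_R", "ELBOW_L", "ELBOW_R",
  "WRIST_L", "WRIST_R", "HAND_L", "HAND_R",
  "HIP_L", "HIP_R", "KNEE_L", "KNEE_R",
  "ANKLE_L", "ANKLE_R", "FOOT_L", "FOOT_R"
)

#' Coordinate column names for a joint set
#'
#' Expands joint names into the `<JOINT>_x`, `<JOINT>_y`, `<JOINT>_z`
#' column triplets used in recording files and frame matrices.
#'
#' @param joints character vector of joint names (default all 20).
#' @return character vector of length `3 * length(joints)`.
#' @export
joint_columns <- function(joints = JOINT_NAMES) {
  as.vector(t(outer(joints, c("x", "y", "z"), paste, sep = "_")))
}

#' @keywords internal
joint_xyz <- function(joint) paste(joint, c("x", "y", "z"), sep = "_")

#' Extract one joint's trajectory from a recording
#'
#' @param rec a [recording()].
#' @param joint joint name, one of [JOINT_NAMES].
#' @return numeric matrix (frames x 3) with columns x, y, z in meters.
#' @export
joint_track <- function(rec, joint) {
  joint <- match.arg(joint, JOINT_NAMES)
  m <- as.matrix(rec$frames[, joint_xyz(joint)])
  colnames(m) <- c("x", "y", "z")
  m
}
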