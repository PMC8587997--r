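#' Canonical joint roster
#'
#' Joint labels in the fixed order used throughout the package: six spinal
#' joints followed by the six extremity joints, each split into a
#' standing-side ("-st.") and swinging-side ("-sw.") channel after
#' relabeling. Spinal joints form the "spine" group, shoulder/elbow/wrist
#' the "upper" group and hip/knee/ankle the "lower" group.
#'
#' @param spine character vector of spinal joint labels.
#' @param extremities character vector of extremity base names; each is
#'   expanded into "-st." and "-sw." channels.
#' @return Character vector of joint labels in canonical order.
#' @export
canonical_joints <- function(spine = spine_joint_names(),
                             extremities = extremity_joint_names()) {
  stopifnot(is.character(spine), is.character(extremities))
  c(spine, as.vector(t(outer(extremities, c("-st.", "-sw."), paste0))))
}

#' @rdname canonical_joints
#' @export
spine_joint_names <- function() {
  c("L5S1", "L4L3", "L1T12", "T9T8", "T1C7", "C1Head")
}

#' @rdname canonical_joints
#' @export
extremity_joint_names <- function() {
  c("Shoulder", "Elbow", "Wrist", "Hip", "Knee", "Ankle")
}

#' Movement-plane labels in canonical row order
#'
#' Within each joint the first trajectory is the joint's abduction
#' (frontal plane), the second its rotation (transverse plane) and the
#' third its flexion (sagittal plane).
#'
#' @return Character vector of length 3.
#' @export
plane_names <- function() c("abduction", "rotation", "flexion")

joint_group <- function(joint) {
  base <- sub("-st\\.$|-sw\\.$", "", joint)
  ifelse(base %in% spine_joint_names(), "spine",
         ifelse(base %in% c("Shoulder", "Elbow", "Wrist"), "upper", "lower"))
}

#' Descriptor table for the flattened step-cycle layout
#'
#' A step cycle of `n_timepoints` timepoints, `length(joints)` joints and 3
#' movement planes is flattened joint-major (planes in abduction, rotation,
#' flexion order within each joint; timepoint fastest) into a single row
#' vector. This table is the bijection between the flat column index and
#' the (joint, plane, timepoint) triple; all modules share it.
#'
#' @param joints character vector of joint labels (canonical order).
#' @param n_timepoints number of timepoints per trajectory (default 100).
#' @return A data.frame with columns `flat_index` (1-based), `joint`,
#'   `plane`, `timepoint` (1..n_timepoints, percent of cycle when 100) and
#'   `group` (spine/upper/lower).
#' @examples
#' d <- variable_descriptors()
#' nrow(d)  # 5400 for the full 18-joint, 100-timepoint layout
#' @export
variable_descriptors <- function(joints = canonical_joints(),
                                 n_timepoints = 100L) {
  stopifnot(n_timepoints >= 1)
  planes <- plane_names()
  d <- data.frame(
    flat_index = seq_len(length(joints) * 3L * n_timepoints),
    joint = rep(joints, each = 3L * n_timepoints),
    plane = rep(rep(planes, each = n_timepoints), times = length(joints)),
    timepoint = rep(seq_len(n_timepoints), times = 3L * length(joints)),
    stringsAsFactors = FALSE
  )
  d$group <- joint_group(d$joint)
  d
}

#' Number of flattened variables for a layout
#' @inheritParams variable_descriptors
#' @return Integer count (18 joints, 100 timepoints give 5400).
#' @export
n_variables <- function(joints = canonical_joints(), n_timepoints = 100L) {
  length(joints) * 3L * as.integer(n_timepoints)
}

#' Flatten a timepoints x joints x planes cycle array
#'
#' @param cycle numeric array `n_timepoints x n_joints x 3` with dimnames
#'   on the joint and plane axes matching the canonical layout.
#' @return Numeric vector of length `n_timepoints * n_joints * 3` in
#'   canonical flat order.
#' @export
flatten_cycle <- function(cycle) {
  stopifnot(length(dim(cycle)) == 3L, dim(cycle)[3] == 3L)
  # joint-major, plane next, timepoint fastest
  as.vector(aperm(cycle, c(1L, 3L, 2L)))
}

#' Inverse of [flatten_cycle()]
#' @param x numeric vector in canonical flat order.
#' @param joints joint labels of the layout.
#' @param n_timepoints timepoints per trajectory.
#' @return Array `n_timepoints x n_joints x 3`.
#' @export
unflatten_cycle <- function(x, joints = canonical_joints(),
                            n_timepoints = 100L) {
  stopifnot(length(x) == n_variables(joints, n_timepoints))
  a <- array(x, dim = c(n_timepoints, 3L, length(joints)))
  aperm(a, c(1L, 3L, 2L)) -> out
  dimnames(out) <- list(NULL, joints, plane_names())
  out
}
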