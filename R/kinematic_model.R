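# Lower-extremity linked rigid-body model and forward kinematics.
#
# Conventions (lab frame): right-handed, X = walking direction, Y = subject's
# left, Z = up.  Marker positions in millimetres.  Joint angles are exposed in
# degrees at every API surface and converted to radians only inside rotation
# construction.  The reference (zero) configuration is an anatomical standing
# pose with straight knees: segment longitudinal axes point along -Z, feet
# along +X.  Each segment frame has its origin at the joint connecting it to
# its parent, axes aligned with the lab frame at zero pose.

#' Names and ordering of the 22 pose-vector entries
#'
#' The pose vector `q` has a fixed documented layout:
#' entries 1-3 pelvis translation (mm), 4-6 pelvis orientation (deg:
#' anterior tilt, obliquity, axial rotation), then for the right and the left
#' side in turn: hip flexion, hip adduction, hip internal rotation, knee
#' flexion, knee adduction, knee internal rotation, ankle dorsiflexion,
#' subtalar inversion (all deg).  Flexion, adduction, internal rotation,
#' dorsiflexion and inversion are positive on both sides (axes are mirrored
#' right/left).
#'
#' @return Character vector of length 22.
#' @export
pose_names <- function() {
  side <- function(s) paste0(c("hip_flexion", "hip_adduction", "hip_rotation",
                               "knee_flexion", "knee_adduction", "knee_rotation",
                               "ankle_dorsiflexion", "subtalar_inversion"), "_", s)
  c("pelvis_tx", "pelvis_ty", "pelvis_tz",
    "pelvis_tilt", "pelvis_obliquity", "pelvis_rotation",
    side("R"), side("L"))
}

#' Default (nominal) segment lengths
#'
#' @return Named numeric vector of the seven length parameters, mm.
#' @export
default_lengths <- function() {
  c(pelvic_width = 240, thigh_L = 410, thigh_R = 410,
    shank_L = 400, shank_R = 400, foot_L = 250, foot_R = 250)
}

# Rotation matrix for a rotation of `deg` degrees about unit axis `ax`
# (Rodrigues formula).  Axes used in the model are signed coordinate axes.
rot_axis <- function(ax, deg) {
  th <- deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

# DOF axes for one body side; sgn = +1 for left, -1 for right, so that
# adduction (toward the midline), internal rotation and inversion are
# positive on both sides.  Flexion is about -Y at the hip and ankle
# (dorsiflexion) and +Y at the knee, identical for both sides.
.side_axes <- function(sgn) {
  list(
    hip      = cbind(c(0, -1, 0), c(sgn, 0, 0), c(0, 0, sgn)),
    knee     = cbind(c(0, 1, 0),  c(sgn, 0, 0), c(0, 0, sgn)),
    ankle    = cbind(c(0, -1, 0)),
    subtalar = cbind(c(sgn, 0, 0))
  )
}

#' Build the 22-DOF lower-extremity model
#'
#' Constructs the 9-segment kinematic tree (pelvis; femur, shank, talus and
#' foot per side) with the given segment lengths.  Joints: a free 6-DOF
#' pelvis-to-lab joint, 3-DOF hips, 3-DOF knees, 1-DOF ankles
#' (plantar/dorsiflexion) and 1-DOF subtalar joints (eversion/inversion);
#' 22 DOF in total.  Three-DOF joints apply an intrinsic Cardan sequence
#' flexion -> adduction -> internal rotation.
#'
#' @param lengths Named numeric vector with entries `pelvic_width`,
#'   `thigh_L`, `thigh_R`, `shank_L`, `shank_R`, `foot_L`, `foot_R` (mm).
#'   Defaults to [default_lengths()].  All must be strictly positive.
#' @return An object of class `gait_model`.
#' @export
build_model <- function(lengths = default_lengths()) {
  need <- names(default_lengths())
  if (!all(need %in% names(lengths)))
    stop("missing length parameter(s): ",
         paste(setdiff(need, names(lengths)), collapse = ", "))
  lengths <- lengths[need]
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all segment lengths must be finite and strictly positive")

  pw <- lengths[["pelvic_width"]]
  talus_h <- 10  # fixed nominal talus height, mm (massless intermediate body)

  seg <- function(name, parent, offset, joint_name, dof_names, axes, q_idx)
    list(name = name, parent = parent, joint_offset = offset,
         joint_name = joint_name, dof_names = dof_names,
         axes = axes, q_idx = q_idx)

  qn <- pose_names()
  segments <- list(
    pelvis = seg("pelvis", NA_character_, c(0, 0, 0), "pelvis_free",
                 qn[4:6],
                 cbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)), 4:6)
  )
  sides <- list(R = list(sgn = -1, q0 = 6), L = list(sgn = +1, q0 = 14))
  for (s in names(sides)) {
    sgn <- sides[[s]]$sgn; q0 <- sides[[s]]$q0
    ax <- .side_axes(sgn)
    segments[[paste0("femur_", s)]] <- seg(
      paste0("femur_", s), "pelvis", c(0, sgn * pw / 2, 0),
      paste0("hip_", s), qn[q0 + 1:3], ax$hip, q0 + 1:3)
    segments[[paste0("shank_", s)]] <- seg(
      paste0("shank_", s), paste0("femur_", s),
      c(0, 0, -lengths[[paste0("thigh_", s)]]),
      paste0("knee_", s), qn[q0 + 4:6], ax$knee, q0 + 4:6)
    segments[[paste0("talus_", s)]] <- seg(
      paste0("talus_", s), paste0("shank_", s),
      c(0, 0, -lengths[[paste0("shank_", s)]]),
      paste0("ankle_", s), qn[q0 + 7], ax$ankle, q0 + 7)
    segments[[paste0("foot_", s)]] <- seg(
      paste0("foot_", s), paste0("talus_", s), c(0, 0, -talus_h),
      paste0("subtalar_", s), qn[q0 + 8], ax$subtalar, q0 + 8)
  }

  structure(list(lengths = lengths, segments = segments,
                 talus_height = talus_h, q_names = qn),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat("gait_model: 9 segments,", n_dof(x), "DOF\n")
  cat("lengths (mm):\n"); print(round(x$lengths, 1))
  invisible(x)
}

#' Total number of degrees of freedom of a model
#' @param model A `gait_model`.
#' @return Integer DOF count (6 pelvis + joint DOF).
#' @export
n_dof <- function(model) {
  3L + sum(vapply(model$segments, function(s) length(s$q_idx), integer(1)))
}

.check_q <- function(model, q) {
  if (length(q) != 22)
    stop("pose vector must have exactly 22 entries, got ", length(q))
  q <- as.numeric(q)
  if (any(!is.finite(q))) stop("pose vector contains non-finite entries")
  names(q) <- model$q_names
  q
}

#' Segment poses (forward kinematics)
#'
#' Computes the rigid transform of every segment frame in the lab frame for a
#' given pose.  The pelvis pose is the free-joint transform; each child pose
#' is the parent pose composed with the joint-centre translation and the
#' joint's ordered axis rotations.
#'
#' @param model A `gait_model`.
#' @param q Pose vector, length 22 (see [pose_names()]); angles in degrees,
#'   translations in mm.
#' @return Named list (one entry per segment) of `list(R = 3x3 rotation,
#'   t = origin, mm)`.
#' @export
segment_poses <- function(model, q) {
  q <- .check_q(model, q)
  poses <- vector("list", length(model$segments))
  names(poses) <- names(model$segments)
  for (nm in names(model$segments)) {
    sg <- model$segments[[nm]]
    Rj <- diag(3)
    for (k in seq_along(sg$q_idx))
      Rj <- Rj %*% rot_axis(sg$axes[, k], q[[sg$q_idx[k]]])
    if (is.na(sg$parent)) {           # pelvis: free joint
      poses[[nm]] <- list(R = Rj, t = as.numeric(q[1:3]))
    } else {
      pp <- poses[[sg$parent]]
      poses[[nm]] <- list(R = pp$R %*% Rj,
                          t = as.numeric(pp$t + pp$R %*% sg$joint_offset))
    }
  }
  poses
}

#' Predict marker positions from a pose
#'
#' Applies each marker's constant segment-frame offset through the forward
#' kinematics: `position = R_segment %*% offset + t_segment`.
#'
#' @param model A `gait_model`.
#' @param attachments Marker attachment table: data.frame with columns
#'   `name`, `segment`, `ox`, `oy`, `oz` (offset, mm).
#' @param q Pose vector, length 22.
#' @return Numeric matrix, one row per marker (rownames = marker names,
#'   attachment order preserved), columns X/Y/Z, mm.
#' @export
predict_markers <- function(model, attachments, q) {
  attachments <- as_attachments(attachments)
  unknown <- setdiff(unique(attachments$segment), names(model$segments))
  if (length(unknown))
    stop("attachment references unknown segment(s): ",
         paste(unknown, collapse = ", "))
  poses <- segment_poses(model, q)
  out <- matrix(NA_real_, nrow(attachments), 3,
                dimnames = list(attachments$name, c("X", "Y", "Z")))
  for (sgm in unique(attachments$segment)) {
    i <- which(attachments$segment == sgm)
    off <- t(as.matrix(attachments[i, c("ox", "oy", "oz")]))
    p <- poses[[sgm]]
    out[i, ] <- t(p$R %*% off + p$t)
  }
  out
}

# Validate / canonicalize an attachment table.
as_attachments <- function(x) {
  if (inherits(x, "marker_protocol")) x <- x$markers
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("name", "segment", "ox", "oy", "oz")
  if (!all(need %in% names(x)))
    stop("attachment table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(x$name)) stop("duplicate marker names in attachment table")
  off <- as.matrix(x[, c("ox", "oy", "oz")])
  if (any(!is.finite(off))) stop("non-finite marker offsets")
  x
}
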