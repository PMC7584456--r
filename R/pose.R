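# Rigid-body poses: rotation + translation applied to a ligand's input
# frame. Ligand conformers generated by the synthetic module are
# centred at the origin, so the rotation part of a perturbation turns
# the ligand in place about its own centroid.

#' Construct a rigid pose
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation 3-vector (Angstrom).
#' @return object of class `RigidPose`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == 3),
            length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be orthonormal with det +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidPose")
}

#' Apply a pose to coordinates or a Structure
#' @param x an n x 3 matrix or a `Structure`.
#' @param pose a `RigidPose`.
#' @return transformed object of the same type (all models moved).
#' @export
apply_pose <- function(x, pose) {
  if (inherits(x, "Structure")) {
    x$models <- lapply(x$models, function(m) {
      sweep(tcrossprod(m, pose$rotation), 2, pose$translation, "+")
    })
    return(x)
  }
  sweep(tcrossprod(x, pose$rotation), 2, pose$translation, "+")
}

#' Compose two poses
#' @param outer,inner `RigidPose` objects; the result applies `inner`
#'   first, then `outer`.
#' @return a `RigidPose`.
#' @export
compose_poses <- function(outer, inner) {
  rigid_pose(
    outer$rotation %*% inner$rotation,
    as.vector(outer$rotation %*% inner$translation) + outer$translation
  )
}

#' Invert a pose
#' @param pose a `RigidPose`.
#' @return the inverse `RigidPose`.
#' @export
invert_pose <- function(pose) {
  Rt <- t(pose$rotation)
  rigid_pose(Rt, -as.vector(Rt %*% pose$translation))
}

#' Pose for a rotation about an arbitrary axis
#' @param axis 3-vector rotation axis.
#' @param angle_deg rotation angle (degrees, right-handed).
#' @param center point the axis passes through (default origin).
#' @return a `RigidPose`.
#' @export
axis_rotation_pose <- function(axis, angle_deg, center = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  rigid_pose(R, as.numeric(center - R %*% center))
}

#' Random rigid-body perturbation of a pose
#'
#' Adds a translation drawn uniformly from the ball of radius
#' `max_trans` and a rotation about a uniformly random axis by an angle
#' uniform in \[0, `max_rot`\] degrees (applied about the ligand-frame
#' origin, i.e. the ligand centroid for synthetic ligands). The docking
#' protocol ramps these magnitudes from 3 A / 8 deg down to 1 A / 3 deg.
#'
#' @param pose a `RigidPose`.
#' @param max_trans maximal translation (Angstrom, >= 0).
#' @param max_rot maximal rotation angle (degrees, >= 0).
#' @param seed optional integer; when given, the draw is a deterministic
#'   function of the seed.
#' @return perturbed `RigidPose`.
#' @export
perturb_pose <- function(pose, max_trans, max_rot, seed = NULL) {
  stopifnot(max_trans >= 0, max_rot >= 0)
  if (!is.null(seed)) set.seed(seed)
  # uniform in ball by radius ~ U^(1/3)
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  dt <- u * max_trans * stats::runif(1)^(1 / 3)
  a <- stats::rnorm(3)
  a <- a / sqrt(sum(a^2))
  ang <- stats::runif(1, 0, max_rot)
  R <- rotation_matrix(a, ang)
  rigid_pose(R %*% pose$rotation,
             as.vector(R %*% pose$translation) + dt)
}

# Deterministic ordering key for tie-breaks.
pose_hash <- function(pose) {
  paste(signif(c(pose$rotation, pose$translation), 10), collapse = ",")
}
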