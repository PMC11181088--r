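# Pose records: 19 named 3D joints (mesh/camera frame), a global body
# rotation, and optional per-joint rotations. Joint order is fixed by the
# canonical label list; loaders re-sort by label.

#' Canonical body joint labels
#'
#' The fixed 19-joint order used throughout: ankles, knees, hips, wrists,
#' elbows, shoulders, neck, head, nose, eyes, ears (left before right).
#' Fingers, toes and jaw are excluded.
#'
#' @return Character vector of length 19.
#' @export
pose_joint_labels <- function() {
  c("left_ankle", "right_ankle", "left_knee", "right_knee",
    "left_hip", "right_hip", "left_wrist", "right_wrist",
    "left_elbow", "right_elbow", "left_shoulder", "right_shoulder",
    "neck", "head", "nose", "left_eye", "right_eye",
    "left_ear", "right_ear")
}

#' Construct a pose record
#'
#' @param image_id Stimulus identifier (character scalar).
#' @param joints3d 19 x 3 numeric matrix of joint coordinates in the viewer
#'   (camera) frame; rownames must be a permutation of [pose_joint_labels()]
#'   and are re-sorted into canonical order.
#' @param global_rotation 3x3 rotation matrix for the body's global
#'   orientation (orthonormal, det +1, tolerance 1e-6).
#' @param joint_rotations Optional named list of 19 unit quaternions
#'   (per-joint rotations), re-sorted like the joints.
#' @return A `pose_record` object.
#' @export
pose_record <- function(image_id, joints3d, global_rotation,
                        joint_rotations = NULL) {
  labels <- pose_joint_labels()
  if (!is.character(image_id) || length(image_id) != 1L || is.na(image_id)) {
    stop("image_id must be a single character string", call. = FALSE)
  }
  if (!is.matrix(joints3d) || ncol(joints3d) != 3L || anyNA(joints3d)) {
    stop("joints3d must be a numeric K x 3 matrix without NAs", call. = FALSE)
  }
  if (is.null(rownames(joints3d))) {
    if (nrow(joints3d) != length(labels)) {
      stop(sprintf("expected %d joints, got %d", length(labels),
                   nrow(joints3d)), call. = FALSE)
    }
    rownames(joints3d) <- labels
  }
  if (!setequal(rownames(joints3d), labels) ||
      nrow(joints3d) != length(labels)) {
    bad <- setdiff(rownames(joints3d), labels)
    stop(sprintf("joint labels must be exactly the canonical 19 (unexpected: %s)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  joints3d <- joints3d[labels, , drop = FALSE]
  assert_rotation_matrix(global_rotation)
  if (!is.null(joint_rotations)) {
    if (!setequal(names(joint_rotations), labels) ||
        length(joint_rotations) != length(labels)) {
      stop("joint_rotations must be named by the canonical 19 joint labels",
           call. = FALSE)
    }
    joint_rotations <- joint_rotations[labels]
    ok <- vapply(joint_rotations, is_unit_quaternion, logical(1))
    if (!all(ok)) {
      stop(sprintf("non-unit joint rotation for: %s",
                   paste(labels[!ok], collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(image_id = image_id,
                 joints3d = joints3d,
                 global_rotation = global_rotation,
                 joint_rotations = joint_rotations),
            class = "pose_record")
}

#' @export
print.pose_record <- function(x, ...) {
  cat("<pose_record>", x$image_id, "-", nrow(x$joints3d), "joints,",
      if (is.null(x$joint_rotations)) "no" else "with", "joint rotations\n")
  invisible(x)
}

#' Orthographic projection of a pose to 2D
#'
#' Drops the depth coordinate: the 2D view-dependent parameterization keeps
#' the first two coordinates of each joint.  No camera intrinsics are
#' modeled.
#'
#' @param pose A [pose_record()].
#' @return 19 x 2 matrix of image-plane joint coordinates, canonical order.
#' @export
project_to_2d <- function(pose) {
  stopifnot(inherits(pose, "pose_record"))
  pose$joints3d[, 1:2, drop = FALSE]
}

#' Undo the global body rotation (view-independent parameterization)
#'
#' Applies the inverse global rotation to every joint, aligning all poses to
#' a common canonical orientation so that two poses differing only in
#' viewpoint coincide.  No further centering or scaling is applied.
#'
#' @param pose A [pose_record()].
#' @return 19 x 3 matrix of aligned joint coordinates.
#' @export
align_view_independent <- function(pose) {
  stopifnot(inherits(pose, "pose_record"))
  R <- pose$global_rotation
  assert_rotation_matrix(R)
  # R^{-1} = R' for a rotation; J_aligned = R^{-1} J per joint (column vector)
  aligned <- pose$joints3d %*% R # (J' R)' rowwise == R' J
  dimnames(aligned) <- dimnames(pose$joints3d)
  aligned
}

#' Mean per-joint position error (MPJPE)
#'
#' The mean over joints of the Euclidean distance between corresponding
#' joints of two poses, the standard dissimilarity in the 3D joint
#' estimation literature.  Works for 2D or 3D joint sets.
#'
#' @param a,b K x d numeric matrices (d = 2 or 3) in matching joint order.
#' @return Nonnegative scalar.
#' @export
mean_per_joint_distance <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b))) {
    stop(sprintf("joint sets must share dimensions (got %s vs %s)",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  if (!ncol(a) %in% c(2L, 3L)) {
    stop("joints must be 2- or 3-dimensional", call. = FALSE)
  }
  mean(sqrt(rowSums((a - b)^2)))
}
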