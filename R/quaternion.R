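# Unit quaternions in (w, x, y, z) order with a canonical sign (w >= 0;
# if w == 0 the first nonzero of x, y, z is positive) so that serialized
# rotations are deterministic despite the q / -q double cover.

#' Construct a unit quaternion
#'
#' Quaternions are stored as numeric vectors `c(w, x, y, z)` of class
#' `"quaternion"`, normalized to unit length and canonical sign.
#'
#' @param w,x,y,z Real components; the scalar part is `w`.
#' @return A unit `quaternion`.
#' @export
quaternion <- function(w, x, y, z) {
  q <- c(w, x, y, z)
  if (!is.numeric(q) || length(q) != 4L || anyNA(q)) {
    stop("quaternion requires four finite numeric components", call. = FALSE)
  }
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("cannot normalize a zero quaternion", call. = FALSE)
  q <- q / n
  q <- canonical_quaternion_sign(q)
  structure(q, names = c("w", "x", "y", "z"), class = "quaternion")
}

canonical_quaternion_sign <- function(q) {
  nz <- which(abs(q) > 0)
  if (length(nz) && q[nz[1L]] < 0) q <- -q
  q
}

is_unit_quaternion <- function(q, tol = 1e-6) {
  is.numeric(q) && length(q) == 4L && !anyNA(q) && abs(sum(q^2) - 1) <= tol
}

assert_rotation_matrix <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || anyNA(R)) {
    stop("global rotation must be a 3x3 numeric matrix", call. = FALSE)
  }
  ortho_err <- max(abs(crossprod(R) - diag(3)))
  if (ortho_err > tol) {
    stop(sprintf("matrix is not orthonormal (max |R'R - I| = %.2e)", ortho_err),
         call. = FALSE)
  }
  d <- det(R)
  if (abs(d - 1) > tol) {
    stop(sprintf("matrix determinant is %.6f, not +1 (improper rotation)", d),
         call. = FALSE)
  }
  invisible(R)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Uses Shepperd's method: the largest of the four squared components is
#' recovered from the trace/diagonal first, so the division below is always
#' well conditioned.  The result carries the canonical sign convention
#' (`w >= 0`).
#'
#' @param R A 3x3 rotation matrix (orthonormal, determinant +1, checked to
#'   tolerance `1e-6`).
#' @return A unit [quaternion()] that reproduces `R` on conversion back.
#' @seealso [quaternion_to_rotation_matrix()]
#' @export
rotation_matrix_to_quaternion <- function(R) {
  assert_rotation_matrix(R)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  # candidate 4*q_i^2 values
  cand <- c(1 + tr,
            1 + R[1, 1] - R[2, 2] - R[3, 3],
            1 - R[1, 1] + R[2, 2] - R[3, 3],
            1 - R[1, 1] - R[2, 2] + R[3, 3])
  i <- which.max(cand)
  s <- sqrt(cand[i]) # = 2*|q_i|
  q <- switch(i,
    c(s / 2,
      (R[3, 2] - R[2, 3]) / (2 * s),
      (R[1, 3] - R[3, 1]) / (2 * s),
      (R[2, 1] - R[1, 2]) / (2 * s)),
    c((R[3, 2] - R[2, 3]) / (2 * s),
      s / 2,
      (R[1, 2] + R[2, 1]) / (2 * s),
      (R[1, 3] + R[3, 1]) / (2 * s)),
    c((R[1, 3] - R[3, 1]) / (2 * s),
      (R[1, 2] + R[2, 1]) / (2 * s),
      s / 2,
      (R[2, 3] + R[3, 2]) / (2 * s)),
    c((R[2, 1] - R[1, 2]) / (2 * s),
      (R[1, 3] + R[3, 1]) / (2 * s),
      (R[2, 3] + R[3, 2]) / (2 * s),
      s / 2))
  quaternion(q[1], q[2], q[3], q[4])
}

#' Convert a unit quaternion back to its rotation matrix
#'
#' @param q A unit quaternion `(w, x, y, z)`.
#' @return The corresponding 3x3 rotation matrix.
#' @export
quaternion_to_rotation_matrix <- function(q) {
  if (!is_unit_quaternion(q)) {
    stop("q must be a unit quaternion (w, x, y, z)", call. = FALSE)
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Angular distance between two 3D rotations (viewpoint dissimilarity)
#'
#' The geodesic-style metric `acos(|qa . qb|)` on unit quaternions.  The
#' absolute value makes the metric well defined under the quaternion double
#' cover (q and -q encode the same rotation), bounding it by pi/2; the dot
#' product is clamped to `[-1, 1]` before `acos` so numerically identical
#' rotations return exactly 0.
#'
#' @param qa,qb Unit quaternions `(w, x, y, z)`.
#' @return Dissimilarity in radians, in `[0, pi/2]`.
#' @export
viewpoint_distance <- function(qa, qb) {
  if (!is_unit_quaternion(qa) || !is_unit_quaternion(qb)) {
    stop("viewpoint_distance requires unit quaternions", call. = FALSE)
  }
  d <- abs(sum(qa * qb))
  acos(min(max(d, -1), 1))
}

#' Mean per-joint rotation distance between two joint-rotation lists
#'
#' Averages [viewpoint_distance()] over the K joints of two poses; used as
#' the joint rotation-based view-independent pose dissimilarity.
#'
#' @param Qa,Qb Lists of K unit quaternions in matching joint order.
#' @return Mean angular distance in radians.
#' @export
joint_rotation_distance <- function(Qa, Qb) {
  if (length(Qa) != length(Qb)) {
    stop(sprintf("joint rotation lists differ in length (%d vs %d)",
                 length(Qa), length(Qb)), call. = FALSE)
  }
  mean(vapply(seq_along(Qa),
              function(k) viewpoint_distance(Qa[[k]], Qb[[k]]),
              numeric(1)))
}

#' Draw rotations uniformly on SO(3)
#'
#' Normalized 4-dimensional standard Gaussians are exactly uniform on the
#' unit quaternion sphere, hence uniform on the rotation group.
#'
#' @param n Number of rotations.
#' @return A list of `n` unit quaternions.
#' @export
random_rotations <- function(n) {
  lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    quaternion(q[1], q[2], q[3], q[4])
  })
}
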