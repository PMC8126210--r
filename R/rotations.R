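# Rotation algebra: elementary rotations, orthonormality checks, projection
# to SO(3), Euler (Tait-Bryan) extraction with a configurable sequence.

#' Elementary rotation matrices
#'
#' Right-handed rotations about the body axes. Axes follow the package
#' convention: x lateral (flexion/extension axis), y cranial (axial-rotation
#' axis, the neck-stick direction at the upright calibration posture),
#' z antero-posterior (lateral-bending axis).
#'
#' @param angle rotation angle in radians.
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_x <- function(angle) rotation_about(1L, angle)

#' @rdname rotation_x
#' @export
rotation_y <- function(angle) rotation_about(2L, angle)

#' @rdname rotation_x
#' @export
rotation_z <- function(angle) rotation_about(3L, angle)

rotation_about <- function(axis, angle) {
  c0 <- cos(angle); s0 <- sin(angle)
  switch(axis,
    matrix(c(1, 0, 0, 0, c0, s0, 0, -s0, c0), 3, 3),
    matrix(c(c0, 0, -s0, 0, 1, 0, s0, 0, c0), 3, 3),
    matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3))
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues' formula for the rotation by `angle` about unit vector `axis`.
#'
#' @param axis 3-vector (normalized internally).
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle) {
  n <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Test a matrix for membership in SO(3)
#'
#' @param R candidate 3x3 matrix.
#' @param tol Frobenius-norm tolerance on `t(R) %*% R - I` and on
#'   `det(R) - 1`.
#' @return logical.
#' @export
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    sqrt(sum((crossprod(R) - diag(3))^2)) < tol &&
    abs(det(R) - 1) < tol
}

assert_rotation <- function(R, what = "rotation") {
  if (!is_rotation(R))
    ns_stop("neckstick_invalid_rotation",
            "%s is not a proper rotation matrix (orthonormal, det +1)", what)
  invisible(R)
}

#' Project a matrix to the nearest rotation
#'
#' Orthogonal polar factor via SVD, with the sign of the smallest singular
#' direction flipped if needed to land in SO(3). Used for the chordal mean of
#' orientations over a calibration window.
#'
#' @param M 3x3 matrix.
#' @return nearest (Frobenius) 3x3 rotation matrix.
#' @export
project_rotation <- function(M) {
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Draw a uniformly distributed random rotation
#'
#' QR-based Haar sampling; used in property tests and the free-movement task.
#'
#' @param n number of rotations.
#' @return a 3x3 matrix if `n == 1`, else a 3x3xn array.
#' @export
random_rotation <- function(n = 1L) {
  one <- function() {
    qrd <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
    if (det(Q) < 0) Q[, 3] <- -Q[, 3]
    Q
  }
  if (n == 1L) return(one())
  out <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) out[, , i] <- one()
  out
}

axis_index <- function(ch) match(ch, c("x", "y", "z"))

parse_sequence <- function(sequence) {
  ax <- axis_index(strsplit(sequence, "")[[1]])
  if (length(ax) != 3L || anyNA(ax) || anyDuplicated(ax))
    ns_stop("neckstick_bad_sequence",
            "Euler sequence must be three distinct axes from {x,y,z}, got '%s'",
            sequence)
  ax
}

#' Extract Euler angles from a rotation matrix
#'
#' Intrinsic Tait-Bryan decomposition `R = R_i(a1) R_j(a2) R_k(a3)` for any
#' sequence of three distinct axes. The default sequence `"xzy"` places
#' lateral inclination (rotation about the antero-posterior z axis) in the
#' intermediate slot: during physiological neck motion its magnitude stays
#' far below 90 degrees, which keeps the decomposition away from gimbal lock.
#'
#' @param R 3x3 rotation matrix.
#' @param sequence three-letter axis string, e.g. `"xzy"` (default), `"zxy"`.
#' @param gimbal_tol error if the intermediate angle is within this distance
#'   (radians) of +/- 90 degrees.
#' @return numeric 3-vector of angles in radians, in sequence order.
#' @export
euler_from_rotation <- function(R, sequence = "xzy", gimbal_tol = 1e-6) {
  assert_rotation(R, "R")
  ax <- parse_sequence(sequence)
  i <- ax[1]; j <- ax[2]; k <- ax[3]
  s <- (i - j) * (j - k) * (k - i) / 2  # Levi-Civita sign of the sequence
  x <- min(1, max(-1, s * R[i, k]))
  a2 <- asin(x)
  if (abs(abs(a2) - pi / 2) < gimbal_tol)
    ns_stop("neckstick_gimbal_lock",
            "intermediate Euler angle is within tolerance of +/-90 degrees (gimbal lock)")
  a1 <- atan2(-s * R[j, k], R[k, k])
  a3 <- atan2(-s * R[i, j], R[i, i])
  c(a1, a2, a3)
}

#' Compose a rotation from Euler angles
#'
#' Inverse of [euler_from_rotation()]: `R = R_i(a1) R_j(a2) R_k(a3)` with the
#' intrinsic axis order given by `sequence`.
#'
#' @param angles numeric 3-vector, radians, in sequence order.
#' @param sequence three-letter axis string (default `"xzy"`).
#' @return 3x3 rotation matrix.
#' @export
rotation_from_euler <- function(angles, sequence = "xzy") {
  ax <- parse_sequence(sequence)
  rotation_about(ax[1], angles[1]) %*%
    rotation_about(ax[2], angles[2]) %*%
    rotation_about(ax[3], angles[3])
}
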