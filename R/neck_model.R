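# The two-joint neck model: neck-stick vector, predicted and measured head
# position, and protraction.
#
# Model summary: two ball joints, J1 near vertebra C7 and J2 near vertebra
# C2, joined by a rigid neck-stick of length l12. The stick direction is the
# y axis of the neck rigid body's orientation. The head center is J2, so the
# head position relative to the thorax is fully determined by the thorax and
# neck orientations plus l12 (five degrees of freedom: rotation about the
# stick axis is shared between the joints).

#' Neck model parameters
#'
#' The seven unknowns of the extended identification model: the neck-stick
#' length `l12`, the thorax vector `vs1` from the sternum-body origin to
#' joint J1 (constant in the sternum frame), and the head vector `v2h` from
#' joint J2 to the head-body origin on the forehead (constant in the head
#' frame).
#'
#' @param l12 neck-stick length, meters, > 0.
#' @param vs1 numeric 3-vector, meters, sternum frame.
#' @param v2h numeric 3-vector, meters, head frame.
#' @return an object of class `neck_parameters`.
#' @export
neck_parameters <- function(l12, vs1 = c(0, 0, 0), v2h = c(0, 0, 0)) {
  l12 <- as.numeric(l12); vs1 <- as.numeric(vs1); v2h <- as.numeric(v2h)
  stopifnot(length(l12) == 1L, length(vs1) == 3L, length(v2h) == 3L)
  if (!is.finite(l12) || l12 <= 0)
    ns_stop("neckstick_bad_params", "l12 must be a positive finite length, got %g", l12)
  if (!all(is.finite(c(vs1, v2h))))
    ns_stop("neckstick_bad_params", "vs1 and v2h must be finite")
  structure(list(l12 = l12, vs1 = vs1, v2h = v2h), class = "neck_parameters")
}

#' @export
print.neck_parameters <- function(x, ...) {
  cat(sprintf("<neck_parameters> l12 = %.2f mm\n", m_to_mm(x$l12)))
  cat("  vs1 (mm):", format(round(m_to_mm(x$vs1), 2)), "\n")
  cat("  v2h (mm):", format(round(m_to_mm(x$v2h), 2)), "\n")
  invisible(x)
}

#' Neck-stick vector
#'
#' The stick from J1 to J2 is `l12` times the y axis of the neck rigid
#' body's orientation (its second column): the body-frame direction
#' `(0, 1, 0)` mapped into the frame the orientation is expressed in.
#'
#' @param neck_orientation 3x3 rotation of the neck body.
#' @param l12 stick length, meters.
#' @return numeric 3-vector, same frame as `neck_orientation`, norm `l12`.
#' @export
neck_stick_vector <- function(neck_orientation, l12) {
  assert_rotation(neck_orientation, "neck orientation")
  stopifnot(is.finite(l12), l12 > 0)
  l12 * neck_orientation[, 2]
}

as_rotation <- function(x) if (inherits(x, "pose")) x$rotation else x

#' Predicted head position (forward model)
#'
#' Predicts the head-body origin in the sternum frame as the three-term sum
#' `vs1 + v12 + v2h`, each expressed in the sternum frame: the thorax
#' vector, the neck-stick vector (neck body's y axis scaled by `l12`), and
#' the head vector rotated by the head orientation relative to the sternum.
#'
#' @param params a [neck_parameters()].
#' @param neck_orientation 3x3 rotation of the neck body (calibrated,
#'   earth/lab frame).
#' @param sternum_pose sternum [pose()] or its 3x3 rotation (same frame).
#' @param head_orientation 3x3 rotation of the head body (same frame).
#' @return predicted head-body origin, numeric 3-vector, sternum frame,
#'   meters.
#' @export
predict_head_position <- function(params, neck_orientation, sternum_pose,
                                  head_orientation) {
  stopifnot(inherits(params, "neck_parameters"))
  Rs <- as_rotation(sternum_pose)
  assert_rotation(Rs, "sternum orientation")
  assert_rotation(head_orientation, "head orientation")
  v12_s <- crossprod(Rs, neck_stick_vector(neck_orientation, params$l12))
  v2h_s <- crossprod(Rs, head_orientation %*% params$v2h)
  as.numeric(params$vs1 + v12_s + v2h_s)
}

#' Measured head position
#'
#' Expresses the measured head-body origin in the sternum frame from the two
#' lab-frame poses: `R_ls (o_h^l - o_s^l)`, the lab-frame offset between the
#' head and sternum origins rotated into the sternum frame.
#'
#' @param head_pose head [pose()] in the lab frame.
#' @param sternum_pose sternum [pose()] in the same lab frame.
#' @return numeric 3-vector, sternum frame, meters.
#' @export
measured_head_position <- function(head_pose, sternum_pose) {
  stopifnot(inherits(head_pose, "pose"), inherits(sternum_pose, "pose"))
  if (!identical(head_pose$frame, sternum_pose$frame))
    ns_stop("neckstick_frame_mismatch",
            "head pose is in frame '%s' but sternum pose is in frame '%s'",
            head_pose$frame, sternum_pose$frame)
  delta <- pose_position(head_pose) - pose_position(sternum_pose)
  as.numeric(crossprod(sternum_pose$rotation, delta))
}

#' Head protraction from neck and thorax orientations
#'
#' Protraction is the horizontal displacement of J2 relative to J1: the
#' component of the neck-stick vector orthogonal to the thorax "up" vector
#' `u = R_s up_axis`. The scalar protraction equals `l12 * sin(phi)` where
#' `phi` is the angle between the stick and `u`; the protraction vector is
#' `v12 - l12 * u`. Both vanish at the upright calibration posture, where
#' all sensed orientations are identity and the stick is aligned with `u`.
#'
#' @param neck_orientation calibrated 3x3 rotation of the neck body.
#' @param sternum_orientation calibrated 3x3 rotation of the sternum body.
#' @param l12 neck-stick length, meters.
#' @param up_axis thorax-up direction in the calibrated sternum body frame.
#'   Default `c(0, 1, 0)`: the canonical cranial axis, which coincides with
#'   the stick direction at calibration so that protraction is zero there.
#'   Set `c(0, 0, 1)` for an antero-posterior reference instead.
#' @return an object of class `protraction_result`: list with `p_scalar`
#'   (meters, >= 0), `p_vector` (3-vector, meters), `phi` (radians).
#' @export
protraction <- function(neck_orientation, sternum_orientation, l12,
                        up_axis = c(0, 1, 0)) {
  assert_rotation(neck_orientation, "neck orientation")
  assert_rotation(sternum_orientation, "sternum orientation")
  stopifnot(is.finite(l12), l12 > 0)
  v12 <- neck_stick_vector(neck_orientation, l12)
  u <- as.numeric(sternum_orientation %*% (up_axis / sqrt(sum(up_axis^2))))
  along <- sum(v12 * u)
  perp <- v12 - along * u
  phi <- atan2(sqrt(sum(perp^2)), along)
  structure(list(p_scalar = sqrt(sum(perp^2)),
                 p_vector = as.numeric(v12 - l12 * u),
                 phi = phi),
            class = "protraction_result")
}

#' @export
print.protraction_result <- function(x, ...) {
  cat(sprintf("<protraction> p = %.2f mm  (phi = %.2f deg)\n",
              m_to_mm(x$p_scalar), rad_to_deg(x$phi)))
  invisible(x)
}

#' Per-sample protraction series of a calibrated recording
#'
#' @param recording a calibrated [trial_recording()].
#' @param l12 neck-stick length, meters (e.g. from [fit_parameters()] or
#'   [predict_l12()]).
#' @param up_axis see [protraction()].
#' @return data.frame with columns `time_s`, `p_mm`, `phi_deg`, `px_mm`,
#'   `py_mm`, `pz_mm` (protraction vector components, calibrated frame).
#' @export
protraction_series <- function(recording, l12, up_axis = c(0, 1, 0)) {
  if (is.null(recording$calibration))
    ns_warn("neckstick_uncalibrated",
            "recording is not calibrated; protraction assumes identity at upright posture")
  Rn <- body_rotations(recording, "neck")
  Rs <- body_rotations(recording, "sternum")
  n <- n_samples(recording)
  out <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) {
    p <- protraction(Rn[, , i], Rs[, , i], l12, up_axis)
    out[i, ] <- c(p$p_scalar, p$phi, p$p_vector)
  }
  data.frame(time_s = recording$time,
             p_mm = m_to_mm(out[, 1]),
             phi_deg = rad_to_deg(out[, 2]),
             px_mm = m_to_mm(out[, 3]),
             py_mm = m_to_mm(out[, 4]),
             pz_mm = m_to_mm(out[, 5]))
}
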