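# Trial recordings: synchronized marker + pose time series for the head,
# sternum and neck rigid bodies, plus the calibration procedure.

NS_BODIES <- c("head", "sternum", "neck")

#' Construct a trial recording
#'
#' A trial recording holds the synchronized time series of the three tracked
#' rigid bodies (head, sternum, neck): raw marker positions in the lab frame
#' and the 6-DoF poses derived from them. Poses are recomputed from the
#' markers (orthogonal Procrustes per sample) unless supplied.
#'
#' @param time numeric vector of sample times, seconds, strictly increasing.
#' @param markers named list (`head`, `sternum`, `neck`) of N x 9 matrices:
#'   columns are marker1 xyz, marker2 xyz, marker3 xyz in meters, lab frame.
#' @param geometry 3x3 reference marker geometry shared by all tripods
#'   ([tripod_geometry()] by default).
#' @param poses optional named list of per-body pose series, each a list with
#'   `position` (N x 3, meters) and `rotation` (3 x 3 x N).
#' @param truth optional ground-truth payload (simulator output).
#' @param calibration optional named list of per-body 3x3 calibration
#'   rotations already applied to the pose series.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(time, markers, geometry = tripod_geometry(),
                            poses = NULL, truth = NULL, calibration = NULL) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 1L) ns_stop("neckstick_empty_recording", "recording has no samples")
  if (any(diff(time) <= 0))
    ns_stop("neckstick_nonmonotone_time", "sample times must be strictly increasing")
  missing <- setdiff(NS_BODIES, names(markers))
  if (length(missing))
    ns_stop("neckstick_missing_body", "missing body stream(s): %s",
            paste(missing, collapse = ", "))
  for (b in NS_BODIES) {
    markers[[b]] <- as.matrix(markers[[b]])
    if (!all(dim(markers[[b]]) == c(n, 9L)))
      ns_stop("neckstick_bad_markers", "markers$%s must be %d x 9", b, n)
  }
  if (is.null(poses)) poses <- poses_from_markers(markers, geometry)
  rate <- if (n > 1L) 1 / stats::median(diff(time)) else NA_real_
  structure(list(time = time, sample_rate = rate,
                 markers = markers[NS_BODIES], geometry = geometry,
                 poses = poses[NS_BODIES], calibration = calibration,
                 truth = truth),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording: %d samples @ %.5g Hz, %.4g s, %s>\n",
              n_samples(x), x$sample_rate, diff(range(x$time)),
              if (is.null(x$calibration)) "uncalibrated" else "calibrated"))
  invisible(x)
}

#' Number of samples in a recording
#' @param recording a [trial_recording()].
#' @return integer sample count.
#' @export
n_samples <- function(recording) length(recording$time)

#' Per-body pose accessors
#'
#' @param recording a [trial_recording()].
#' @param body `"head"`, `"sternum"` or `"neck"`.
#' @return `body_rotations`: a 3x3xN array; `body_positions`: an N x 3 matrix
#'   of body-origin positions in the lab frame, meters.
#' @export
body_rotations <- function(recording, body) {
  recording$poses[[match.arg(body, NS_BODIES)]]$rotation
}

#' @rdname body_rotations
#' @export
body_positions <- function(recording, body) {
  recording$poses[[match.arg(body, NS_BODIES)]]$position
}

# Lift marker series to pose series, one Procrustes fit per body per sample.
poses_from_markers <- function(markers, geometry) {
  out <- list()
  for (b in names(markers)) {
    M <- markers[[b]]
    n <- nrow(M)
    pos <- matrix(NA_real_, n, 3)
    rot <- array(NA_real_, c(3, 3, n))
    rms <- numeric(n)
    for (i in seq_len(n)) {
      P <- matrix(M[i, ], 3, 3, byrow = TRUE)
      fit <- kabsch(geometry, P)
      pos[i, ] <- fit$t
      rot[, , i] <- fit$R
      rms[i] <- fit$rms
    }
    out[[b]] <- list(position = pos, rotation = rot, rms = rms)
  }
  out
}

# Marker positions implied by a pose series (used by the simulator and by
# position-noise injection round trips).
markers_from_poses <- function(poses, geometry) {
  out <- list()
  for (b in names(poses)) {
    pos <- poses[[b]]$position
    rot <- poses[[b]]$rotation
    n <- nrow(pos)
    M <- matrix(NA_real_, n, 9)
    for (i in seq_len(n)) {
      pts <- geometry %*% t(rot[, , i]) +
        matrix(pos[i, ], 3, 3, byrow = TRUE)
      M[i, ] <- as.numeric(t(pts))
    }
    out[[b]] <- M
  }
  out
}

chordal_mean <- function(rotations, idx = seq_len(dim(rotations)[3])) {
  project_rotation(apply(rotations[, , idx, drop = FALSE], c(1, 2), mean))
}

rotation_angle <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
}

#' Estimate calibration rotations from a static window
#'
#' At the calibration time the participant holds an upright posture and the
#' sensed orientations of all bodies are redefined to identity. This function
#' averages each body's orientation over the window (chordal mean: matrix
#' mean projected onto the nearest rotation) and returns the left-composition
#' rotations that map those means to identity. Relative orientations between
#' bodies at any other time are unchanged up to these fixed rotations.
#'
#' @param recording a [trial_recording()].
#' @param window `c(t_start, t_end)` in seconds; must contain at least one
#'   sample.
#' @param spread_warn_deg warn (class `neckstick_calibration_spread`) if any
#'   body's orientation deviates from its window mean by more than this many
#'   degrees — the participant was probably not static.
#' @return an object of class `neck_calibration`: a named list of per-body
#'   3x3 rotations.
#' @seealso [apply_calibration()]
#' @export
calibrate <- function(recording, window = c(0, 1), spread_warn_deg = 2) {
  idx <- which(recording$time >= window[1] & recording$time <= window[2])
  if (!length(idx))
    ns_stop("neckstick_empty_window",
            "calibration window [%g, %g] s contains no samples", window[1], window[2])
  out <- list()
  for (b in NS_BODIES) {
    rot <- body_rotations(recording, b)
    Rm <- chordal_mean(rot, idx)
    spread <- max(vapply(idx, function(i)
      rotation_angle(crossprod(Rm, rot[, , i])), numeric(1)))
    if (spread > deg_to_rad(spread_warn_deg))
      ns_warn("neckstick_calibration_spread",
              "body '%s' moved %.2f deg within the calibration window (threshold %g deg)",
              b, rad_to_deg(spread), spread_warn_deg)
    out[[b]] <- t(Rm)
  }
  structure(out, class = "neck_calibration", window = window)
}

#' Apply calibration rotations to a recording
#'
#' Left-composes each body's orientation series with its calibration
#' rotation, so the sensed orientations are identity (on average) over the
#' calibration window. Positions and markers are untouched.
#'
#' @param recording a [trial_recording()].
#' @param calibration a `neck_calibration` from [calibrate()].
#' @return a calibrated [trial_recording()].
#' @export
apply_calibration <- function(recording, calibration) {
  stopifnot(inherits(calibration, "neck_calibration"))
  for (b in NS_BODIES) {
    rot <- recording$poses[[b]]$rotation
    C <- calibration[[b]]
    for (i in seq_len(dim(rot)[3])) rot[, , i] <- C %*% rot[, , i]
    recording$poses[[b]]$rotation <- rot
  }
  recording$calibration <- calibration
  recording
}

#' Calibrate a recording in one step
#'
#' Convenience wrapper: [calibrate()] on `window` then [apply_calibration()].
#'
#' @inheritParams calibrate
#' @return a calibrated [trial_recording()].
#' @export
calibrate_recording <- function(recording, window = c(0, 1),
                                spread_warn_deg = 2) {
  apply_calibration(recording,
                    calibrate(recording, window, spread_warn_deg))
}
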