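# Linear least-squares identification of the seven model parameters and
# residual-error summaries.
#
# The prediction error is linear in (vs1, l12, v2h): for every sample t the
# predicted sternum-frame head position is
#   vs1  +  l12 * u_n(t)  +  R_hs(t) v2h
# with u_n(t) the neck body's y axis expressed in the sternum frame and
# R_hs(t) the head orientation relative to the sternum. Stacking one 3x7
# block per sample against the measured position (Eq.-5 style offset) gives
# an overdetermined linear system solved in a single step.

PARAM_NAMES <- c("vs1_x", "vs1_y", "vs1_z", "l12", "v2h_x", "v2h_y", "v2h_z")

# Relative kinematics of one recording: stick direction in s-frame, head
# orientation relative to s, and the measured sternum-frame head position.
relative_kinematics <- function(recording) {
  n <- n_samples(recording)
  Rh <- body_rotations(recording, "head")
  Rs <- body_rotations(recording, "sternum")
  Rn <- body_rotations(recording, "neck")
  ph <- body_positions(recording, "head")
  ps <- body_positions(recording, "sternum")
  u_n <- matrix(NA_real_, n, 3)
  Rhs <- array(NA_real_, c(3, 3, n))
  meas <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    RsT <- t(Rs[, , i])
    u_n[i, ] <- RsT %*% Rn[, 2, i]
    Rhs[, , i] <- RsT %*% Rh[, , i]
    meas[i, ] <- RsT %*% (ph[i, ] - ps[i, ])
  }
  list(u_n = u_n, Rhs = Rhs, measured = meas, time = recording$time)
}

#' Build the stacked linear system for parameter identification
#'
#' For each sample the 3x7 coefficient block is
#' `[ I3 | u_n(t) | R_hs(t) ]` with unknown ordering
#' `(vs1 x,y,z, l12, v2h x,y,z)`; the observation block is the measured
#' sternum-frame head position. `N` samples give a `3N x 7` system.
#'
#' @param recording a calibrated [trial_recording()] with all three body
#'   streams present.
#' @return list with `A` (`3N x 7` matrix, columns named), `b` (length `3N`),
#'   `n_samples`.
#' @export
build_design_matrix <- function(recording) {
  stopifnot(inherits(recording, "trial_recording"))
  kin <- relative_kinematics(recording)
  n <- nrow(kin$u_n)
  A <- matrix(0, 3 * n, 7)
  b <- numeric(3 * n)
  I3 <- diag(3)
  for (i in seq_len(n)) {
    r <- (3 * i - 3) + 1:3
    A[r, 1:3] <- I3
    A[r, 4] <- kin$u_n[i, ]
    A[r, 5:7] <- kin$Rhs[, , i]
    b[r] <- kin$measured[i, ]
  }
  colnames(A) <- PARAM_NAMES
  list(A = A, b = b, n_samples = n)
}

#' Identify the seven neck-model parameters by linear least squares
#'
#' Pools all trials of one participant (the study procedure) into one
#' stacked linear system and solves it with a rank-revealing orthogonal
#' decomposition (QR; rank and conditioning assessed by SVD with tolerance
#' `max singular value * 1e-10`). Requires rank 7, i.e. the trials must
#' contain at least two distinct neck orientations and two distinct
#' head-to-sternum orientations; a static-only recording raises an
#' identifiability error naming the deficient parameter directions.
#'
#' @param recordings a [trial_recording()] or list of them (all calibrated,
#'   same participant).
#' @return an object of class `neck_fit`: list with `params`
#'   ([neck_parameters()]), `per_axis_residuals` (data.frame from
#'   [residual_stats()]), `n_samples`, `condition_number`, `rank`,
#'   `residuals` (N x 3 matrix, meters, predicted minus measured).
#' @export
fit_parameters <- function(recordings) {
  if (inherits(recordings, "trial_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1L)
  sys <- lapply(recordings, build_design_matrix)
  A <- do.call(rbind, lapply(sys, `[[`, "A"))
  b <- unlist(lapply(sys, `[[`, "b"), use.names = FALSE)
  n <- sum(vapply(sys, `[[`, integer(1), "n_samples"))
  if (n < 3L)
    ns_stop("neckstick_too_few_samples",
            "at least 3 samples (9 scalar equations) are needed for 7 unknowns")

  sv <- svd(A, nu = 0)
  tol <- sv$d[1] * 1e-10
  rank <- sum(sv$d > tol)
  if (rank < 7L) {
    deficient <- apply(abs(sv$v[, sv$d <= tol, drop = FALSE]), 2,
                       function(w) PARAM_NAMES[which.max(w)])
    ns_stop("neckstick_unidentifiable",
            paste0("design matrix rank %d < 7: motion does not excite all ",
                   "parameters (deficient direction(s) dominated by: %s). ",
                   "Static-only data cannot separate vs1, l12 and v2h."),
            rank, paste(unique(deficient), collapse = ", "))
  }
  theta <- qr.coef(qr(A), b)
  params <- neck_parameters(l12 = theta[4], vs1 = theta[1:3], v2h = theta[5:7])
  resid <- matrix(A %*% theta - b, ncol = 3, byrow = TRUE)
  meas <- matrix(b, ncol = 3, byrow = TRUE)
  structure(list(params = params,
                 per_axis_residuals = residual_stats(meas + resid, meas),
                 n_samples = n,
                 condition_number = sv$d[1] / sv$d[7],
                 rank = rank,
                 residuals = resid),
            class = "neck_fit")
}

#' @export
print.neck_fit <- function(x, ...) {
  cat(sprintf("<neck_fit> %d samples, condition number %.3g\n",
              x$n_samples, x$condition_number))
  print(x$params)
  print(x$per_axis_residuals, row.names = FALSE)
  invisible(x)
}

#' Per-axis residual summary (mean error and 5%/95% percentiles)
#'
#' Signed per-axis errors are `predicted - measured`, reported in
#' millimeters as the mean error (ME) and the 5% and 95% percentiles
#' (linear interpolation between order statistics).
#'
#' @param predicted N x 3 matrix, meters.
#' @param measured N x 3 matrix, meters, same dimensions.
#' @return data.frame with columns `axis` (`"x"`, `"y"`, `"z"`), `me_mm`,
#'   `p5_mm`, `p95_mm`.
#' @export
residual_stats <- function(predicted, measured) {
  predicted <- as.matrix(predicted); measured <- as.matrix(measured)
  if (!nrow(predicted))
    ns_stop("neckstick_empty_series", "cannot summarize an empty series")
  if (!all(dim(predicted) == dim(measured)))
    ns_stop("neckstick_length_mismatch",
            "predicted and measured series must have equal dimensions")
  err_mm <- m_to_mm(predicted - measured)
  qs <- apply(err_mm, 2, stats::quantile, probs = c(0.05, 0.95),
              names = FALSE, type = 7)
  data.frame(axis = c("x", "y", "z"),
             me_mm = colMeans(err_mm),
             p5_mm = qs[1, ],
             p95_mm = qs[2, ])
}

#' Model-predicted head-position series for a recording
#'
#' Applies the forward model sample by sample under fixed parameters.
#'
#' @param params a [neck_parameters()].
#' @param recording a calibrated [trial_recording()].
#' @return N x 3 matrix of predicted sternum-frame head positions, meters.
#' @export
predicted_head_series <- function(params, recording) {
  kin <- relative_kinematics(recording)
  n <- nrow(kin$u_n)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    out[i, ] <- params$vs1 + params$l12 * kin$u_n[i, ] +
      kin$Rhs[, , i] %*% params$v2h
  }
  out
}

#' Measured head-position series for a recording
#'
#' @param recording a [trial_recording()].
#' @return N x 3 matrix of measured sternum-frame head positions, meters.
#' @export
measured_head_series <- function(recording) {
  relative_kinematics(recording)$measured
}

#' Predicted J2 (head-center) trajectory
#'
#' The model's head center is joint J2: `vs1 + l12 * u_n(t)` in the sternum
#' frame. Linear in `l12`, so perturbing the length by `delta` moves J2 by
#' exactly `delta` along the instantaneous stick direction.
#'
#' @param params a [neck_parameters()] (only `vs1` and `l12` used).
#' @param recording a calibrated [trial_recording()].
#' @return N x 3 matrix, sternum frame, meters.
#' @export
j2_series <- function(params, recording) {
  kin <- relative_kinematics(recording)
  sweep(params$l12 * kin$u_n, 2, params$vs1, "+")
}
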