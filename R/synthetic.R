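# Synthetic motion-capture simulator: ground-truth two-joint motion and
# marker trajectories emulating standardized head-movement tasks (zigzag and
# cross pursuit patterns in neutral or protracted head position, free
# movement, static sitting), with configurable additive marker-position and
# orientation noise. Every trial is generated from known model parameters,
# so exact-recovery and sensitivity experiments have a known truth.

#' Specify a head-movement task
#'
#' Tasks parameterize joint-angle trajectories directly: pursuit patterns
#' (`zigzag`, `cross`) are piecewise gaze targets in (yaw, pitch) tracked
#' with minimum-jerk transitions and repeated `repetitions` times;
#' `free` is band-limited random motion on all three axes; `static` holds
#' the calibration posture. In `protracted` head-position mode a constant
#' protraction angle offset is added to the neck joint after the calibration
#' lead-in while the head keeps tracking the gaze targets, translating the
#' head forward at level gaze.
#'
#' @param pattern `"zigzag"`, `"cross"`, `"free"` or `"static"`.
#' @param head_mode `"neutral"` or `"protracted"`.
#' @param repetitions pattern repetitions (pursuit tasks), default 3.
#' @param duration_s trial duration for `free`/`static` (defaults 30 s and
#'   10 s); for pursuit tasks the duration follows from `segment_s`.
#' @param amplitude_deg named amplitudes in degrees:
#'   `flexion` (pitch, about x), `lateral` (lateral bending, about z),
#'   `axial` (yaw, about y). Physiological bounds are enforced
#'   (<= 80 / 45 / 80 degrees).
#' @param segment_s duration of one minimum-jerk segment between gaze
#'   waypoints, seconds.
#' @return an object of class `task_spec`.
#' @export
task_spec <- function(pattern = c("zigzag", "cross", "free", "static"),
                      head_mode = c("neutral", "protracted"),
                      repetitions = 3L,
                      duration_s = NULL,
                      amplitude_deg = c(flexion = 30, lateral = 10, axial = 20),
                      segment_s = 0.8) {
  pattern <- match.arg(pattern)
  head_mode <- match.arg(head_mode)
  amp <- amplitude_deg[c("flexion", "lateral", "axial")]
  if (anyNA(amp))
    ns_stop("neckstick_bad_task", "amplitude_deg must name flexion, lateral, axial")
  lim <- c(flexion = 80, lateral = 45, axial = 80)
  if (any(abs(amp) > lim))
    ns_stop("neckstick_amplitude", "amplitude outside physiological range: %s",
            paste(names(amp)[abs(amp) > lim], collapse = ", "))
  if (is.null(duration_s))
    duration_s <- switch(pattern, free = 30, static = 10, NA_real_)
  structure(list(pattern = pattern, head_mode = head_mode,
                 repetitions = as.integer(repetitions),
                 duration_s = duration_s,
                 amplitude = deg_to_rad(amp), segment_s = segment_s),
            class = "task_spec")
}

#' Simulator configuration
#'
#' @param true_params ground-truth [neck_parameters()].
#' @param anthro optional one-row anthropometrics data.frame.
#' @param sample_rate sampling rate, Hz (default 120).
#' @param marker_noise_sd iid Gaussian SD per marker coordinate, meters
#'   (default 1e-4 m = 0.1 mm, typical optoelectronic precision).
#' @param orientation_noise_sd SD of the orientation-noise angle, radians
#'   (default 0: optical pipelines derive orientation from the markers).
#' @param seed integer RNG seed for the noise draws.
#' @param geometry tripod reference geometry, [tripod_geometry()].
#' @param neck_share fraction of the gaze rotation carried by the neck
#'   joint chain (remainder is head-on-neck rotation).
#' @param thorax_share fraction of the neck-chain rotation executed by the
#'   thorax instead of the neck joint (movement-distribution heterogeneity;
#'   default 0).
#' @param neck_wobble_deg amplitudes (degrees) of the slow band-limited
#'   variation in how motion distributes between the neck joint and the
#'   upper cervical spine, about the flexion (x) and lateral-bending (z)
#'   axes. This independent neck-vs-head variation is what makes the stick
#'   length identifiable in practice; without it the neck direction is a
#'   deterministic function of the head orientation and the length is only
#'   weakly excited. Zero during static trials.
#' @param protraction_offset_deg constant neck protraction angle in
#'   `protracted` head mode, degrees (default 25).
#' @param calibration_lead_s static upright lead-in included at the start of
#'   every trial, seconds; this is the calibration window.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(true_params,
                       anthro = NULL,
                       sample_rate = 120,
                       marker_noise_sd = 1e-4,
                       orientation_noise_sd = 0,
                       seed = 1L,
                       geometry = tripod_geometry(),
                       neck_share = 0.6,
                       thorax_share = 0,
                       neck_wobble_deg = c(flexion = 10, lateral = 8),
                       protraction_offset_deg = 25,
                       calibration_lead_s = 1) {
  stopifnot(inherits(true_params, "neck_parameters"),
            sample_rate > 0, marker_noise_sd >= 0, orientation_noise_sd >= 0,
            neck_share >= 0, neck_share <= 1,
            thorax_share >= 0, thorax_share <= 1)
  structure(list(true_params = true_params, anthro = anthro,
                 sample_rate = sample_rate,
                 marker_noise_sd = marker_noise_sd,
                 orientation_noise_sd = orientation_noise_sd,
                 seed = as.integer(seed), geometry = geometry,
                 neck_share = neck_share, thorax_share = thorax_share,
                 neck_wobble = deg_to_rad(neck_wobble_deg),
                 protraction_offset = deg_to_rad(protraction_offset_deg),
                 calibration_lead_s = calibration_lead_s),
            class = "sim_config")
}

# Minimum-jerk interpolation through waypoints; returns values at times tt
# for a piecewise track with one segment of length seg between consecutive
# waypoints. wp: matrix, one waypoint per row.
min_jerk_track <- function(wp, seg, tt) {
  nseg <- nrow(wp) - 1L
  total <- nseg * seg
  out <- matrix(NA_real_, length(tt), ncol(wp))
  for (ii in seq_along(tt)) {
    t0 <- min(max(tt[ii], 0), total - 1e-12)
    k <- floor(t0 / seg)
    tau <- (t0 - k * seg) / seg
    s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    out[ii, ] <- wp[k + 1, ] + s * (wp[k + 2, ] - wp[k + 1, ])
  }
  out
}

# Gaze waypoints in normalized (yaw, pitch) units for one repetition.
pattern_waypoints <- function(pattern) {
  switch(pattern,
    zigzag = rbind(c(0, 0), c(-1, 1), c(-0.5, -1), c(0, 1),
                   c(0.5, -1), c(1, 1), c(0, 0)),
    cross = rbind(c(0, 0), c(0, 1), c(0, 0), c(0, -1), c(0, 0),
                  c(-1, 0), c(0, 0), c(1, 0), c(0, 0)))
}

# Band-limited pseudo-random angle track: sum of K sinusoids, frequencies in
# [0.05, 0.4] Hz, soft-started so the trial begins at rest.
free_track <- function(tt, amp, k = 5L) {
  f <- stats::runif(k, 0.05, 0.4)
  ph <- stats::runif(k, 0, 2 * pi)
  w <- abs(stats::rnorm(k)); w <- w / sum(w)
  raw <- rowSums(sapply(seq_len(k), function(j)
    w[j] * sin(2 * pi * f[j] * tt + ph[j]) - w[j] * sin(ph[j])))
  ramp <- pmin(1, tt / 2)^2
  amp * raw * ramp
}

# Joint-angle time series for a task: gaze pitch/yaw/roll plus the neck
# protraction offset, all starting from rest at the calibration posture.
task_angles <- function(task, config) {
  rate <- config$sample_rate
  lead <- config$calibration_lead_s
  if (task$pattern %in% c("zigzag", "cross")) {
    wp1 <- pattern_waypoints(task$pattern)
    wp <- wp1
    for (r in seq_len(task$repetitions - 1L))
      wp <- rbind(wp, wp1[-1, , drop = FALSE])
    move_dur <- (nrow(wp) - 1L) * task$segment_s
    dur <- lead + move_dur
    tt <- seq(0, dur, by = 1 / rate)
    g <- min_jerk_track(wp, task$segment_s, tt - lead)
    g[tt < lead, ] <- 0
    yaw <- g[, 1] * task$amplitude["axial"]
    pitch <- g[, 2] * task$amplitude["flexion"]
    roll <- numeric(length(tt))
  } else if (task$pattern == "free") {
    dur <- lead + task$duration_s
    tt <- seq(0, dur, by = 1 / rate)
    t0 <- pmax(tt - lead, 0)
    pitch <- free_track(t0, task$amplitude["flexion"])
    yaw <- free_track(t0, task$amplitude["axial"])
    roll <- free_track(t0, task$amplitude["lateral"])
  } else { # static
    dur <- lead + task$duration_s
    tt <- seq(0, dur, by = 1 / rate)
    pitch <- yaw <- roll <- numeric(length(tt))
  }
  offset <- numeric(length(tt))
  if (task$head_mode == "protracted") {
    tau <- pmin(pmax((tt - lead) / 1.0, 0), 1)  # 1 s minimum-jerk ramp-in
    offset <- config$protraction_offset * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  }
  # slow variation of the motion distribution across the cervical spine:
  # extra neck-joint rotation (compensated by the upper cervical joints so
  # the gaze track is unchanged); absent when sitting still
  wob_x <- wob_z <- numeric(length(tt))
  if (task$pattern != "static") {
    t0w <- pmax(tt - lead, 0)
    wob_x <- free_track(t0w, config$neck_wobble[1], k = 4L)
    wob_z <- free_track(t0w, config$neck_wobble[2], k = 4L)
  }
  list(time = tt, pitch = unname(pitch), yaw = unname(yaw),
       roll = unname(roll), offset = offset,
       wobble_x = unname(wob_x), wobble_z = unname(wob_z))
}

# True body poses in the lab frame for given joint angles. The gaze rotation
# is split: the neck chain carries neck_share of it, of which thorax_share
# is executed by the sternum body; the head body always tracks the full
# gaze. Protraction offsets only the neck joint.
true_poses <- function(angles, config) {
  p <- config$true_params
  n <- length(angles$time)
  ts <- config$thorax_share
  ns <- config$neck_share
  p_s <- c(0, 0, 0)
  out <- list()
  for (b in NS_BODIES)
    out[[b]] <- list(position = matrix(NA_real_, n, 3),
                     rotation = array(NA_real_, c(3, 3, n)))
  for (i in seq_len(n)) {
    pit_n <- ns * angles$pitch[i]; yaw_n <- ns * angles$yaw[i]
    Rse <- rotation_x(ts * pit_n) %*% rotation_y(ts * yaw_n)
    Rns <- rotation_x((1 - ts) * pit_n + angles$offset[i] + angles$wobble_x[i]) %*%
      rotation_z(angles$wobble_z[i]) %*%
      rotation_y((1 - ts) * yaw_n)
    Rne <- Rse %*% Rns
    Rhe <- rotation_x(angles$pitch[i]) %*% rotation_y(angles$yaw[i]) %*%
      rotation_z(angles$roll[i])
    ohs <- p$vs1 + as.numeric(crossprod(Rse, neck_stick_vector(Rne, p$l12))) +
      as.numeric(crossprod(Rse, Rhe %*% p$v2h))
    out$sternum$position[i, ] <- p_s
    out$sternum$rotation[, , i] <- Rse
    out$neck$position[i, ] <- p_s + as.numeric(Rse %*% p$vs1) +
      as.numeric(Rne %*% c(0, p$l12 / 2, 0))
    out$neck$rotation[, , i] <- Rne
    out$head$position[i, ] <- p_s + as.numeric(Rse %*% ohs)
    out$head$rotation[, , i] <- Rhe
  }
  out
}

#' Simulate one motion-capture trial
#'
#' Generates smooth ground-truth neck/head/sternum trajectories realizing a
#' task, computes exact marker positions of the three tripods from the
#' forward model, adds iid Gaussian marker noise (and optionally orientation
#' noise on the derived poses), and returns the resulting recording with the
#' ground truth retained alongside (`$truth`: true pose series, parameters,
#' joint-angle series, task).
#'
#' Every trial starts with a static upright lead-in of
#' `config$calibration_lead_s` seconds — the calibration window.
#'
#' @param task a [task_spec()].
#' @param config a [sim_config()].
#' @return a [trial_recording()] (uncalibrated) with `$truth` attached.
#' @export
simulate_trial <- function(task, config) {
  stopifnot(inherits(task, "task_spec"), inherits(config, "sim_config"))
  # separate RNG streams so the ground-truth trajectory does not change when
  # the noise settings do
  angles <- with_seed(derive_seed(config$seed, 101L), task_angles(task, config))
  truth_poses <- true_poses(angles, config)
  markers <- markers_from_poses(truth_poses, config$geometry)
  rec <- with_seed(derive_seed(config$seed, 102L), {
    if (config$marker_noise_sd > 0)
      for (b in NS_BODIES)
        markers[[b]] <- markers[[b]] +
          stats::rnorm(length(markers[[b]]), 0, config$marker_noise_sd)
    r <- trial_recording(angles$time, markers, geometry = config$geometry)
    if (config$orientation_noise_sd > 0)
      r <- add_orientation_noise(r, config$orientation_noise_sd, seed = NULL)
    r
  })
  rec$truth <- list(params = config$true_params, poses = truth_poses,
                    angles = angles, task = task, config = config)
  rec
}

#' Add iid Gaussian position noise to the marker data of a recording
#'
#' Perturbs every marker coordinate of every sample independently and
#' recomputes the body poses from the noised markers. `sd = 0` returns the
#' recording unchanged. Sample count, timing and body labels are preserved.
#'
#' @param recording a [trial_recording()].
#' @param sd noise SD, meters.
#' @param seed optional integer seed (`NULL`: use the current RNG stream).
#' @return a [trial_recording()].
#' @export
add_position_noise <- function(recording, sd, seed = NULL) {
  stopifnot(sd >= 0)
  if (sd == 0) return(recording)
  with_seed(seed, {
    markers <- recording$markers
    for (b in NS_BODIES)
      markers[[b]] <- markers[[b]] + stats::rnorm(length(markers[[b]]), 0, sd)
    out <- trial_recording(recording$time, markers,
                           geometry = recording$geometry,
                           truth = recording$truth)
    if (!is.null(recording$calibration))
      out <- apply_calibration(out, recording$calibration)
    out
  })
}

#' Add iid Gaussian noise to the measured body positions of a recording
#'
#' Perturbs the derived body-origin positions (the position half of each
#' tripod's 6-DoF measurement) per coordinate per sample; orientations and
#' raw marker data are untouched. `sd = 0` returns the recording unchanged.
#'
#' @param recording a [trial_recording()].
#' @param sd noise SD, meters.
#' @param seed optional integer seed (`NULL`: use the current RNG stream).
#' @return a [trial_recording()].
#' @export
noise_body_positions <- function(recording, sd, seed = NULL) {
  stopifnot(sd >= 0)
  if (sd == 0) return(recording)
  with_seed(seed, {
    for (b in NS_BODIES) {
      pos <- recording$poses[[b]]$position
      recording$poses[[b]]$position <- pos + stats::rnorm(length(pos), 0, sd)
    }
    recording
  })
}

#' Add orientation noise to the derived poses of a recording
#'
#' Per body and sample, left-composes the orientation with a random rotation
#' whose axis is uniform on the sphere and whose angle is |N(0, sd)|. Marker
#' data and positions are untouched (this emulates noise entering at the
#' orientation-measurement stage). `sd = 0` returns the recording unchanged.
#'
#' @param recording a [trial_recording()].
#' @param sd angle SD, radians.
#' @param seed optional integer seed (`NULL`: use the current RNG stream).
#' @return a [trial_recording()].
#' @export
add_orientation_noise <- function(recording, sd, seed = NULL) {
  stopifnot(sd >= 0)
  if (sd == 0) return(recording)
  with_seed(seed, {
    for (b in NS_BODIES) {
      rot <- recording$poses[[b]]$rotation
      n <- dim(rot)[3]
      ax <- matrix(stats::rnorm(3 * n), n, 3)
      ang <- abs(stats::rnorm(n, 0, sd))
      for (i in seq_len(n))
        rot[, , i] <- rotation_axis_angle(ax[i, ], ang[i]) %*% rot[, , i]
      recording$poses[[b]]$rotation <- rot
    }
    recording
  })
}

#' Generate a synthetic participant cohort
#'
#' Draws anthropometrics from Gaussians matching the reference cohort's
#' means and SDs (C7-S2 50.7 (2.2) cm, C2-C7 5.8 (0.9) cm, height
#' 1.73 (0.09) m, BMI 24.0 (2.4), age 41.1 (11.9) y), truncated at +/- 3 SD,
#' and sets each participant's true neck-stick length on a ground-truth
#' linear law `l12 = beta1 * lC2C7 + beta0` plus Gaussian scatter. Thorax
#' and head offset vectors get small anatomical jitter around nominal
#' values; a per-participant thorax movement share can be randomized to
#' emulate movement-distribution heterogeneity.
#'
#' @param n cohort size (>= 1).
#' @param seed integer seed.
#' @param beta ground-truth `c(beta0, beta1)` of the length law
#'   (meters, dimensionless). Default `c(0.06, 1.0)` puts typical lengths
#'   near 12 cm.
#' @param scatter_sd SD of the length scatter about the law, meters.
#' @param thorax_share_range range from which each participant's thorax
#'   movement share is drawn uniformly (default `c(0, 0)`).
#' @return an object of class `synthetic_cohort`: list of participants,
#'   each a list with `id`, `anthro` (one-row data.frame), `params`
#'   ([neck_parameters()]), `thorax_share`.
#' @export
generate_cohort <- function(n, seed = 1L, beta = c(0.06, 1.0),
                            scatter_sd = 0.01,
                            thorax_share_range = c(0, 0)) {
  stopifnot(n >= 1)
  ref <- list(length_C7S2_cm = c(50.7, 2.2), length_C2C7_cm = c(5.8, 0.9),
              height_m = c(1.73, 0.09), bmi = c(24.0, 2.4),
              age_y = c(41.1, 11.9))
  rtrunc <- function(m, s) {
    repeat {
      x <- stats::rnorm(1, m, s)
      if (abs(x - m) <= 3 * s) return(x)
    }
  }
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- lapply(ref, function(ms) rtrunc(ms[1], ms[2]))
      # keep ordering invariant lC2C7 < lC7S2 (ranges never overlap at 3 SD,
      # but guard anyway)
      if (a$length_C2C7_cm >= a$length_C7S2_cm)
        a$length_C2C7_cm <- a$length_C7S2_cm / 2
      anthro <- data.frame(id = sprintf("S%02d", i),
                           length_C7S2_cm = a$length_C7S2_cm,
                           length_C2C7_cm = a$length_C2C7_cm,
                           height_m = a$height_m, bmi = a$bmi,
                           age_y = a$age_y)
      l12 <- beta[2] * a$length_C2C7_cm / 100 + beta[1] +
        if (scatter_sd > 0) stats::rnorm(1, 0, scatter_sd) else 0
      params <- neck_parameters(
        l12 = max(l12, 0.02),
        vs1 = c(0, 0.10, -0.08) + stats::rnorm(3, 0, 0.005),
        v2h = c(0, 0.07, 0.08) + stats::rnorm(3, 0, 0.005))
      list(id = anthro$id, anthro = anthro, params = params,
           thorax_share = stats::runif(1, thorax_share_range[1],
                                       thorax_share_range[2]))
    }) |> structure(class = "synthetic_cohort")
  })
}

#' Default task battery of the simulator
#'
#' Zigzag and cross pursuit in neutral and protracted head position plus a
#' 30 s free-movement trial.
#'
#' @param repetitions pattern repetitions per pursuit trial.
#' @return named list of [task_spec()]s.
#' @export
standard_tasks <- function(repetitions = 3L) {
  list(zigzag_neutral = task_spec("zigzag", "neutral", repetitions),
       zigzag_protracted = task_spec("zigzag", "protracted", repetitions),
       cross_neutral = task_spec("cross", "neutral", repetitions),
       cross_protracted = task_spec("cross", "protracted", repetitions),
       free = task_spec("free"))
}

#' Simulate and calibrate a participant's task battery
#'
#' Runs [simulate_trial()] for each task with per-trial derived seeds and
#' calibrates every recording on its static lead-in window.
#'
#' @param participant one element of [generate_cohort()] (or a list with
#'   `params` and optional `thorax_share`).
#' @param tasks named list of [task_spec()]s, default [standard_tasks()].
#' @param seed integer master seed for this participant's noise draws.
#' @param ... passed to [sim_config()] (e.g. `marker_noise_sd`,
#'   `sample_rate`).
#' @return named list of calibrated [trial_recording()]s.
#' @export
simulate_participant <- function(participant, tasks = standard_tasks(),
                                 seed = 1L, ...) {
  dots <- list(...)
  if (is.null(dots$thorax_share) && !is.null(participant$thorax_share))
    dots$thorax_share <- participant$thorax_share
  recs <- list()
  for (k in seq_along(tasks)) {
    cfg <- do.call(sim_config, c(list(true_params = participant$params,
                                      anthro = participant$anthro,
                                      seed = derive_seed(seed, k)),
                                 dots))
    rec <- simulate_trial(tasks[[k]], cfg)
    # the lead-in is static by construction; orientation jitter there is
    # marker noise, not participant movement, so the spread warning is moot
    recs[[names(tasks)[k]]] <- withCallingHandlers(
      calibrate_recording(rec, window = c(0, cfg$calibration_lead_s)),
      neckstick_calibration_spread = function(w) invokeRestart("muffleWarning"))
  }
  recs
}
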