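# Shared fixtures: canonical parameters, small task batteries, and a
# recording builder independent of the package's marker synthesis.

canonical_params <- function() {
  neck_parameters(l12 = 0.12,
                  vs1 = c(0.01, 0.10, -0.08),
                  v2h = c(0.005, 0.07, 0.08))
}

# reduced battery for fast tests: one pursuit + short free movement
quick_tasks <- function() {
  list(zigzag = task_spec("zigzag", repetitions = 1L),
       free = task_spec("free", duration_s = 8))
}

quick_recordings <- function(params = canonical_params(), seed = 5,
                             marker_noise_sd = 0, sample_rate = 60, ...) {
  simulate_participant(list(params = params), tasks = quick_tasks(),
                       seed = seed, marker_noise_sd = marker_noise_sd,
                       sample_rate = sample_rate, ...)
}

# Build a trial_recording from explicit body poses, synthesizing the marker
# table here (independent of the package's internal marker synthesis).
# poses: list per body with `position` (N x 3) and `rotation` (3 x 3 x N).
rec_from_poses <- function(time, poses, geometry = tripod_geometry()) {
  markers <- lapply(poses, function(pb) {
    n <- nrow(pb$position)
    M <- matrix(NA_real_, n, 9)
    for (i in seq_len(n)) {
      pts <- geometry %*% t(pb$rotation[, , i]) +
        matrix(pb$position[i, ], 3, 3, byrow = TRUE)
      M[i, ] <- as.numeric(t(pts))
    }
    M
  })
  trial_recording(time, markers, geometry = geometry)
}

# constant-pose series helper
const_poses <- function(n, head_R = diag(3), head_p = c(0, 0.2, 0.05),
                        sternum_R = diag(3), sternum_p = c(0, 0, 0),
                        neck_R = diag(3), neck_p = c(0, 0.15, -0.02)) {
  rep_pose <- function(R, p)
    list(position = matrix(p, n, 3, byrow = TRUE),
         rotation = array(R, c(3, 3, n)))
  list(head = rep_pose(head_R, head_p),
       sternum = rep_pose(sternum_R, sternum_p),
       neck = rep_pose(neck_R, neck_p))
}

frob <- function(M) sqrt(sum(M^2))
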