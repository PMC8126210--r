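# Coordinate-frame algebra: point/direction transforms, Procrustes pose
# recovery, calibration, Euler extraction.

test_that("transform_point follows the rotate-then-subtract-origin convention", {
  expect_equal(transform_point(c(0, 0, 0), pose()), c(0, 0, 0))
  expect_equal(transform_point(c(1, 2, 3), pose(origin = c(1, 1, 1))),
               c(0, 1, 2))
  p90 <- pose(rotation = rotation_z(pi / 2))
  expect_equal(transform_point(c(1, 0, 0), p90), c(0, 1, 0))
  expect_error(transform_point(c(1, 0, 0), pose(frame = "l"), frame = "e"),
               class = "neckstick_frame_mismatch")
})

test_that("transform_direction omits the origin and preserves norm", {
  p <- pose(origin = c(5, 5, 5))
  expect_equal(transform_direction(c(0, 1, 0), p), c(0, 1, 0))
  expect_equal(transform_direction(c(0, 0, 1),
                                   pose(rotation = rotation_x(pi / 2))),
               c(0, -1, 0))
  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(3)
    pr <- pose(origin = rnorm(3), rotation = random_rotation())
    expect_equal(sqrt(sum(transform_direction(v, pr)^2)), sqrt(sum(v^2)),
                 tolerance = 1e-12)
  }
})

test_that("transforming to a frame and back is the identity", {
  set.seed(7)
  for (i in 1:20) {
    p <- pose(origin = rnorm(3), rotation = random_rotation())
    v <- rnorm(3)
    expect_equal(transform_point(transform_point(v, p), invert_pose(p)), v,
                 tolerance = 1e-12)
  }
})

test_that("pose_from_markers recovers exact rigid transforms", {
  g <- tripod_geometry()
  p0 <- pose_from_markers(g, g)
  expect_equal(p0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(pose_position(p0), c(0, 0, 0), tolerance = 1e-12)
  expect_lt(attr(p0, "rms"), 1e-12)

  R <- rotation_z(pi / 6); t_ <- c(0.1, 0, 0)
  obs <- g %*% t(R) + matrix(t_, 3, 3, byrow = TRUE)
  p1 <- pose_from_markers(obs, g)
  expect_equal(p1$rotation, R, tolerance = 1e-10)
  expect_equal(pose_position(p1), t_, tolerance = 1e-10)
  expect_lt(attr(p1, "rms"), 1e-10)
})

test_that("pose_from_markers is accurate under small marker noise", {
  g <- tripod_geometry()
  set.seed(11)
  ang_err <- pos_err <- numeric(100)
  for (s in 1:100) {
    R <- random_rotation(); t_ <- rnorm(3)
    obs <- g %*% t(R) + matrix(t_, 3, 3, byrow = TRUE) +
      matrix(rnorm(9, 0, 1e-4), 3, 3)
    ph <- pose_from_markers(obs, g)
    pos_err[s] <- sqrt(sum((pose_position(ph) - t_)^2))
    ang_err[s] <- acos(pmin(1, (sum(diag(crossprod(R, ph$rotation))) - 1) / 2))
  }
  expect_lt(mean(pos_err), 0.5e-3)            # 0.5 mm
  expect_lt(mean(ang_err), 0.5 * pi / 180)    # 0.5 degree
})

test_that("collinear markers raise a degenerate-geometry error", {
  line <- rbind(c(0, 0, 0), c(0.05, 0, 0), c(0.1, 0, 0))
  expect_error(pose_from_markers(line, tripod_geometry()),
               class = "neckstick_degenerate_geometry")
})

test_that("calibration maps window-mean orientations to identity", {
  n <- 20
  tt <- seq(0, 1.9, by = 0.1)
  # body at constant rotation Q: calibration must return t(Q)
  Q <- rotation_from_euler(c(0.3, 0.1, -0.2))
  rec <- rec_from_poses(tt, const_poses(n, neck_R = Q))
  cal <- calibrate(rec, window = c(0, 2))
  expect_equal(cal$neck, t(Q), tolerance = 1e-12)
  expect_equal(cal$head, diag(3), tolerance = 1e-12)
  recc <- apply_calibration(rec, cal)
  expect_equal(body_rotations(recc, "neck")[, , 5], diag(3), tolerance = 1e-12)

  # idempotence: calibrating a calibrated recording gives identity rotations
  cal2 <- calibrate(recc, window = c(0, 2))
  for (b in c("head", "sternum", "neck"))
    expect_equal(cal2[[b]], diag(3), tolerance = 1e-9)
})

test_that("calibration averages small wobble to identity (chordal mean)", {
  tt <- seq(0, 1.95, by = 0.05)
  n <- length(tt)
  Q <- rotation_y(0.4)
  set.seed(3)
  poses <- const_poses(n)
  for (i in seq_len(n)) {
    wob <- rotation_from_euler(runif(3, -0.5, 0.5) * pi / 180)
    poses$neck$rotation[, , i] <- wob %*% Q
  }
  rec <- rec_from_poses(tt, poses)
  recc <- suppressWarnings(calibrate_recording(rec, window = c(0, 2)))
  Rm <- project_rotation(apply(body_rotations(recc, "neck"), c(1, 2), mean))
  expect_lt(frob(Rm - diag(3)), 1e-3)
})

test_that("empty calibration windows error and movement warns", {
  rec <- rec_from_poses(seq(0, 1, by = 0.1), const_poses(11))
  expect_error(calibrate(rec, window = c(5, 6)),
               class = "neckstick_empty_window")
  poses <- const_poses(11)
  poses$head$rotation[, , 11] <- rotation_x(5 * pi / 180)
  expect_warning(calibrate(rec_from_poses(seq(0, 1, by = 0.1), poses),
                           window = c(0, 1)),
                 class = "neckstick_calibration_spread")
})

test_that("Euler extraction round-trips away from gimbal lock", {
  expect_equal(euler_from_rotation(diag(3)), c(0, 0, 0))
  expect_equal(euler_from_rotation(rotation_x(pi / 4)), c(pi / 4, 0, 0))
  set.seed(19)
  for (i in 1:1000) {
    ang <- c(runif(1, -2.5, 2.5), runif(1, -80, 80) * pi / 180,
             runif(1, -2.5, 2.5))
    R <- rotation_from_euler(ang)
    expect_lt(frob(rotation_from_euler(euler_from_rotation(R)) - R), 1e-9)
  }
  # the same holds for other sequences
  for (sq in c("zxy", "yzx")) {
    R <- rotation_from_euler(c(0.4, -0.7, 1.1), sequence = sq)
    expect_equal(euler_from_rotation(R, sequence = sq), c(0.4, -0.7, 1.1),
                 tolerance = 1e-10)
  }
})

test_that("gimbal lock at the intermediate angle is a labeled error", {
  R <- rotation_from_euler(c(0.3, pi / 2, -0.2))
  expect_error(euler_from_rotation(R), class = "neckstick_gimbal_lock")
})
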