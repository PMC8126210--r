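# Two-joint model core: stick vector, forward prediction, measured position,
# protraction.

test_that("the neck-stick vector is the neck body's scaled y axis", {
  expect_equal(neck_stick_vector(diag(3), 0.12), c(0, 0.12, 0))
  R <- rotation_x(pi / 6)
  v <- neck_stick_vector(R, 0.12)
  expect_equal(v, as.numeric(R %*% c(0, 0.12, 0)))   # explicit product
  expect_equal(v[2], 0.12 * cos(pi / 6))
  expect_equal(sqrt(sum(v^2)), 0.12)
  set.seed(2)
  for (i in 1:10)
    expect_equal(sqrt(sum(neck_stick_vector(random_rotation(), 0.2)^2)), 0.2,
                 tolerance = 1e-12)
})

test_that("predicted head position is the three-term sum", {
  p <- neck_parameters(0.12, vs1 = c(0, 0.05, 0), v2h = c(0.03, 0.05, 0))
  expect_equal(predict_head_position(p, diag(3), diag(3), diag(3)),
               c(0.03, 0.22, 0))
  p0 <- neck_parameters(0.1)
  expect_equal(predict_head_position(p0, diag(3), diag(3), diag(3)),
               c(0, 0.1, 0))
})

test_that("forward prediction matches a homogeneous-matrix oracle", {
  hom <- function(R, p) rbind(cbind(R, p), c(0, 0, 0, 1))
  oracle <- function(params, Rn, Rs, Rh) {
    J1_e <- as.numeric(Rs %*% params$vs1)
    oh_e <- hom(Rh, as.numeric(hom(Rn, J1_e) %*% c(0, params$l12, 0, 1))[1:3]) %*%
      c(params$v2h, 1)
    as.numeric(hom(t(Rs), c(0, 0, 0)) %*% oh_e)[1:3]
  }
  p <- canonical_params()
  cases <- list(
    list(Rn = rotation_x(pi / 6), Rs = diag(3), Rh = rotation_x(10 * pi / 180)),
    list(Rn = rotation_x(0.3) %*% rotation_y(0.2), Rs = rotation_y(0.1),
         Rh = rotation_from_euler(c(0.5, -0.2, 0.4))))
  for (cs in cases)
    expect_equal(predict_head_position(p, cs$Rn, cs$Rs, cs$Rh),
                 oracle(p, cs$Rn, cs$Rs, cs$Rh), tolerance = 1e-12)
})

test_that("measured head position expresses the offset in the sternum frame", {
  mk <- function(pos, R = diag(3)) pose_at(pos, R, frame = "l")
  expect_equal(measured_head_position(mk(c(0.3, 0.1, 0)), mk(c(0.3, 0.1, 0))),
               c(0, 0, 0))
  expect_equal(measured_head_position(mk(c(0.1, 0.2, 0.3)), mk(c(0, 0, 0))),
               c(0.1, 0.2, 0.3))
  # sternum rotated 90 deg about z with origin (1,0,0), head origin (1,1,0):
  # offset (0,1,0) pulled back through the sternum rotation is (1,0,0)
  expect_equal(measured_head_position(mk(c(1, 1, 0)),
                                      mk(c(1, 0, 0), rotation_z(pi / 2))),
               c(1, 0, 0), tolerance = 1e-12)
  expect_error(measured_head_position(pose_at(frame = "l"), pose_at(frame = "e")),
               class = "neckstick_frame_mismatch")
})

test_that("head position is invariant to rotations of the head about J2", {
  # with v2h = 0 the prediction is the J2 position itself; spinning the head
  # body must not move it
  p <- neck_parameters(0.12, vs1 = c(0.01, 0.1, -0.08), v2h = c(0, 0, 0))
  Rn <- rotation_x(0.4); Rs <- rotation_y(0.1)
  base <- predict_head_position(p, Rn, Rs, diag(3))
  set.seed(8)
  for (i in 1:10)
    expect_equal(predict_head_position(p, Rn, Rs, random_rotation()), base,
                 tolerance = 1e-12)
})

test_that("protraction is zero at calibration and l12*sin(phi) when tilted", {
  pr0 <- protraction(diag(3), diag(3), 0.12)
  expect_equal(pr0$p_scalar, 0)
  expect_equal(pr0$p_vector, c(0, 0, 0))
  expect_equal(pr0$phi, 0)

  pr <- protraction(rotation_x(pi / 6), diag(3), 0.12)
  expect_equal(pr$p_scalar, 0.06, tolerance = 1e-12)    # sin 30 deg = 1/2
  expect_equal(pr$phi, pi / 6, tolerance = 1e-12)
  expect_equal(pr$p_scalar, 0.12 * sin(pr$phi), tolerance = 1e-12)
})

test_that("scalar protraction equals the orthogonal-projection oracle", {
  set.seed(21)
  for (i in 1:25) {
    Rn <- random_rotation(); Rs <- random_rotation()
    l <- runif(1, 0.08, 0.16)
    pr <- protraction(Rn, Rs, l)
    v12 <- l * Rn[, 2]
    u <- Rs %*% c(0, 1, 0)
    perp <- v12 - sum(v12 * u) * u
    expect_equal(pr$p_scalar, sqrt(sum(perp^2)), tolerance = 1e-12)
    expect_equal(pr$p_scalar, l * sin(pr$phi), tolerance = 1e-12)
    expect_equal(pr$p_vector, as.numeric(v12 - l * u), tolerance = 1e-12)
  }
})

test_that("protraction scales linearly with the assumed stick length", {
  Rn <- rotation_x(0.5) %*% rotation_z(0.2); Rs <- rotation_y(0.15)
  base <- protraction(Rn, Rs, 0.12)
  for (a in c(0.7, 1.0, 1.3)) {
    pr <- protraction(Rn, Rs, a * 0.12)
    expect_equal(pr$p_scalar, a * base$p_scalar, tolerance = 1e-12)
    expect_equal(pr$phi, base$phi, tolerance = 1e-12)
  }
})

test_that("protraction_series reports mm/deg columns on a recording", {
  recs <- quick_recordings()
  ps <- protraction_series(recs$zigzag, 0.12)
  expect_named(ps, c("time_s", "p_mm", "phi_deg", "px_mm", "py_mm", "pz_mm"))
  expect_equal(nrow(ps), n_samples(recs$zigzag))
  expect_true(all(ps$p_mm >= 0))
  # during the static lead-in protraction is (near) zero
  expect_lt(max(ps$p_mm[recs$zigzag$time <= 0.9]), 1e-6)
})
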