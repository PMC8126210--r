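# Synthetic motion simulator: generator-model consistency, noise injection
# statistics, cohort generation.

test_that("a static zero-noise trial holds the calibration configuration", {
  p <- canonical_params()
  cfg <- sim_config(p, marker_noise_sd = 0, seed = 2, sample_rate = 30)
  rec <- simulate_trial(task_spec("static", duration_s = 3), cfg)
  for (b in c("head", "sternum", "neck")) {
    M <- rec$markers[[b]]
    expect_lt(max(abs(sweep(M, 2, M[1, ]))), 1e-12)  # constant markers
    expect_equal(body_rotations(rec, b)[, , 10], diag(3), tolerance = 1e-9)
  }
  # head sits at the three-term model sum above the sternum
  expect_equal(body_positions(rec, "head")[1, ],
               p$vs1 + c(0, p$l12, 0) + p$v2h, tolerance = 1e-9)
})

test_that("noiseless simulation is consistent with the forward model", {
  recs <- quick_recordings(marker_noise_sd = 0)
  p <- canonical_params()
  for (rec in recs) {
    meas <- measured_head_series(rec)
    pred <- predicted_head_series(p, rec)
    expect_lt(max(abs(pred - meas)), 1e-10)
  }
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(canonical_params(), marker_noise_sd = 3e-4, seed = 77,
                    sample_rate = 60)
  t1 <- simulate_trial(task_spec("zigzag", repetitions = 1L), cfg)
  t2 <- simulate_trial(task_spec("zigzag", repetitions = 1L), cfg)
  expect_identical(t1$markers, t2$markers)
  expect_identical(t1$poses, t2$poses)
  # free movement draws its trajectory from the config seed too
  f1 <- simulate_trial(task_spec("free", duration_s = 4), cfg)
  f2 <- simulate_trial(task_spec("free", duration_s = 4), cfg)
  expect_identical(f1$markers, f2$markers)
})

test_that("position noise has the configured marginal statistics", {
  cfg <- sim_config(canonical_params(), marker_noise_sd = 0, seed = 4)
  rec <- simulate_trial(task_spec("static", duration_s = 35), cfg)  # 4200 samples
  expect_identical(add_position_noise(rec, 0), rec)
  n1 <- add_position_noise(rec, 1e-3, seed = 9)
  diffs <- unlist(lapply(c("head", "sternum", "neck"),
                         function(b) n1$markers[[b]] - rec$markers[[b]]))
  expect_gt(length(diffs), 1e5)
  expect_equal(sd(diffs), 1e-3, tolerance = 0.02)
  expect_lt(abs(mean(diffs)), 1e-5)
  n2 <- add_position_noise(rec, 1e-3, seed = 10)
  expect_false(identical(n1$markers$head, n2$markers$head))
  # timing and labels preserved
  expect_identical(n1$time, rec$time)
  expect_identical(names(n1$markers), names(rec$markers))
})

test_that("orientation noise matches the small-angle chordal expectation", {
  cfg <- sim_config(canonical_params(), marker_noise_sd = 0, seed = 6)
  rec <- simulate_trial(task_spec("static", duration_s = 100), cfg)
  expect_identical(add_orientation_noise(rec, 0), rec)
  sd_ang <- pi / 180
  no <- add_orientation_noise(rec, sd_ang, seed = 12)
  ds <- numeric(0)
  for (b in c("head", "sternum", "neck")) {
    R0 <- body_rotations(rec, b); R1 <- body_rotations(no, b)
    ds <- c(ds, vapply(seq_len(dim(R0)[3]), function(i)
      frob(R1[, , i] - R0[, , i]), numeric(1)))
    # perturbed orientations stay orthonormal
    expect_lt(frob(crossprod(R1[, , 17]) - diag(3)), 1e-12)
  }
  # E ||R_noise - I||_F ~ sqrt(2) E|angle| = sqrt(2) * sd * sqrt(2/pi)
  expect_equal(mean(ds), 2 * sd_ang / sqrt(pi), tolerance = 0.05)
})

test_that("generate_cohort matches the reference anthropometrics", {
  co0 <- generate_cohort(8, seed = 3, scatter_sd = 0)
  x <- vapply(co0, function(p) p$anthro$length_C2C7_cm, numeric(1))
  y <- vapply(co0, function(p) p$params$l12, numeric(1))
  m <- fit_length_model(x, y, units = "cm")
  expect_equal(m$beta1, 1.0, tolerance = 1e-9)
  expect_equal(m$beta0, 0.06, tolerance = 1e-9)
  expect_equal(m$residual_sd, 0, tolerance = 1e-9)

  co <- generate_cohort(200, seed = 14)
  xc <- vapply(co, function(p) p$anthro$length_C2C7_cm, numeric(1))
  expect_lt(abs(mean(xc) - 5.8), 0.2)
  expect_true(all(vapply(co, function(p)
    p$anthro$length_C2C7_cm < p$anthro$length_C7S2_cm, logical(1))))

  expect_length(generate_cohort(1, seed = 1), 1L)
  expect_s3_class(generate_cohort(1, seed = 1)[[1]]$params, "neck_parameters")
})

test_that("task amplitudes outside physiological bounds are rejected", {
  expect_error(task_spec("zigzag",
                         amplitude_deg = c(flexion = 85, lateral = 10, axial = 20)),
               class = "neckstick_amplitude")
  expect_error(task_spec("free",
                         amplitude_deg = c(flexion = 30, lateral = 50, axial = 20)),
               class = "neckstick_amplitude")
})
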