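# Linear neck-length predictor, cohort descriptives, parametrized-model
# validation.

test_that("fit_length_model recovers exact lines and interpolates two points", {
  x_m <- seq(0.045, 0.075, length.out = 6)
  m <- fit_length_model(x_m, 0.5 * x_m + 0.01, units = "m")
  expect_equal(m$beta1, 0.5, tolerance = 1e-12)
  expect_equal(m$beta0, 0.01, tolerance = 1e-12)
  expect_equal(m$residual_sd, 0, tolerance = 1e-10)

  m2 <- fit_length_model(c(5, 7), c(0.11, 0.13), units = "cm")
  expect_equal(predict_l12(m2, 5), 0.11, tolerance = 1e-12)
  expect_equal(predict_l12(m2, 7), 0.13, tolerance = 1e-12)
  expect_equal(m2$residual_sd, 0)

  expect_error(fit_length_model(c(6, 6, 6), c(0.1, 0.11, 0.12)),
               class = "neckstick_degenerate_predictor")
})

test_that("OLS coefficients match the closed-form oracle on noisy data", {
  set.seed(31)
  x <- rnorm(8, 5.8, 0.9)             # cm
  y <- 1.1 * x / 100 + 0.05 + rnorm(8, 0, 0.01)
  m <- fit_length_model(x, y, units = "cm")
  xm <- x / 100
  b1 <- sum((xm - mean(xm)) * (y - mean(y))) / sum((xm - mean(xm))^2)
  b0 <- mean(y) - b1 * mean(xm)
  expect_equal(m$beta1, b1, tolerance = 1e-12)
  expect_equal(m$beta0, b0, tolerance = 1e-12)
  r <- y - (b0 + b1 * xm)
  expect_equal(m$residual_sd, sqrt(sum(r^2) / 6), tolerance = 1e-12)
  # residuals orthogonal to the predictor
  expect_lt(abs(sum(r * xm)), 1e-10)
})

test_that("predict_l12 converts units and rejects nonphysical output", {
  m1 <- fit_length_model(c(4, 8), c(0.04, 0.08), units = "cm")  # identity law
  expect_equal(predict_l12(m1, 5.8), 0.058, tolerance = 1e-12)
  m2 <- fit_length_model(c(0.05, 0.10), 0.8 * c(0.05, 0.10) + 0.02, units = "m")
  expect_equal(predict_l12(m2, 6.0), 0.068, tolerance = 1e-12)
  # prediction at the cohort mean lies on the line through the centroid
  set.seed(5)
  x <- rnorm(10, 6, 1); y <- 0.012 * x + rnorm(10, 0, 0.005)
  m3 <- fit_length_model(x, y, units = "cm")
  expect_equal(predict_l12(m3, mean(x)), mean(y), tolerance = 1e-12)
  m4 <- fit_length_model(c(5, 10), c(-0.03, 0.07) , units = "cm")
  expect_error(predict_l12(m4, 5), class = "neckstick_nonphysical")
})

test_that("the packaged cohort reproduces the printed descriptive row", {
  an <- read_anthro(system.file("extdata", "participants_reference.csv",
                                package = "neckstick"))
  d <- cohort_descriptives(an)
  g <- function(v, col) d[[col]][d$variable == v]
  expect_equal(g("length_C2C7_cm", "mean"), 5.8)
  expect_equal(g("length_C2C7_cm", "sd"), 0.9)
  expect_equal(g("length_C7S2_cm", "mean"), 50.7)
  expect_equal(g("length_C7S2_cm", "sd"), 2.2)
  expect_equal(g("height_m", "mean"), 1.73)
  expect_equal(g("bmi", "mean"), 24.0)
  expect_equal(g("age_y", "mean"), 41.1)

  one <- cohort_descriptives(an[1, ])
  expect_equal(one$mean[one$variable == "height_m"], 1.61)
  expect_true(all(is.na(one$sd)))
})

test_that("changing l12 moves J2 exactly along the stick direction", {
  p <- canonical_params()
  rec <- quick_recordings(p, marker_noise_sd = 0)$zigzag
  delta <- 0.013
  p2 <- neck_parameters(p$l12 + delta, p$vs1, p$v2h)
  d <- j2_series(p2, rec) - j2_series(p, rec)
  Rn <- body_rotations(rec, "neck"); Rs <- body_rotations(rec, "sternum")
  u <- t(sapply(seq_len(n_samples(rec)), function(i)
    crossprod(Rs[, , i], Rn[, 2, i])))
  expect_equal(d, delta * u, tolerance = 1e-12)
})

test_that("evaluate_parametrized_model summarizes the analytic J2 difference", {
  p <- canonical_params()
  recs <- quick_recordings(p, marker_noise_sd = 0)
  fit <- fit_parameters(recs)

  same <- evaluate_parametrized_model(recs, fit$params$l12, fit)
  expect_lt(max(abs(unlist(same[, -1]))), 1e-9)

  delta <- -0.009
  ev <- evaluate_parametrized_model(recs, fit$params$l12 + delta, fit)
  j2_fit <- do.call(rbind, lapply(recs, function(r) j2_series(fit$params, r)))
  u <- do.call(rbind, lapply(recs, function(r) {
    Rn <- body_rotations(r, "neck"); Rs <- body_rotations(r, "sternum")
    t(sapply(seq_len(n_samples(r)), function(i) crossprod(Rs[, , i], Rn[, 2, i])))
  }))
  expected <- residual_stats(j2_fit + delta * u, j2_fit)
  expect_equal(ev, expected, tolerance = 1e-10)
  expect_error(evaluate_parametrized_model(recs, 0.1, "not a fit"),
               class = "neckstick_missing_reference")
})

test_that("length mis-specification scales protraction proportionally", {
  # the measured-protraction error structure: using alpha * l12 scales the
  # protraction estimate by alpha, i.e. the error is proportional to the
  # true protraction
  recs <- quick_recordings(marker_noise_sd = 0)
  true_p <- protraction_series(recs$free, 0.12)
  for (a in c(0.7, 1.3)) {
    mis <- protraction_series(recs$free, a * 0.12)
    expect_equal(mis$p_mm, a * true_p$p_mm, tolerance = 1e-9)
  }
})
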