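# Anthropometric neck-length predictor: linear model of the identified
# neck-stick length on the palpable C2-C7 distance, cohort descriptives,
# and validation of the parametrized (predicted-length) model against the
# individually fitted model.

#' Participant anthropometrics table
#'
#' Reads a cohort CSV with columns `id`, `length_C7S2_cm`, `length_C2C7_cm`,
#' `height_m`, `bmi`, `age_y`. A packaged eight-participant cohort ships at
#' `system.file("extdata", "participants_reference.csv", package = "neckstick")`.
#'
#' @param path CSV file path.
#' @return data.frame of class `participant_anthro`.
#' @export
read_anthro <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "length_C7S2_cm", "length_C2C7_cm", "height_m", "bmi", "age_y")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    ns_stop("neckstick_parse_error", "anthropometrics file '%s' lacks column(s): %s",
            path, paste(missing, collapse = ", "))
  validate_anthro(df)
  class(df) <- c("participant_anthro", "data.frame")
  df
}

validate_anthro <- function(df) {
  if (any(df$length_C2C7_cm <= 0) || any(df$length_C7S2_cm <= 0))
    ns_stop("neckstick_bad_anthro", "palpated lengths must be positive")
  if (any(df$length_C2C7_cm >= df$length_C7S2_cm))
    ns_stop("neckstick_bad_anthro",
            "C2-C7 length must be smaller than C7-S2 length for every participant")
  invisible(df)
}

#' Cohort descriptive statistics
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of every
#' numeric anthropometric column, optionally rounded to a display precision
#' per column (the reporting convention of cohort tables).
#'
#' @param anthro data.frame from [read_anthro()] (or equivalent columns).
#' @param round_digits named integer vector of display digits per column, or
#'   `NULL` for full precision.
#' @return data.frame with columns `variable`, `mean`, `sd`. For a single
#'   participant the SD is `NA`.
#' @export
cohort_descriptives <- function(anthro,
                                round_digits = c(length_C7S2_cm = 1,
                                                 length_C2C7_cm = 1,
                                                 height_m = 2, bmi = 1,
                                                 age_y = 1)) {
  if (!nrow(anthro))
    ns_stop("neckstick_empty_cohort", "cohort is empty")
  num <- anthro[vapply(anthro, is.numeric, logical(1))]
  out <- data.frame(variable = names(num),
                    mean = vapply(num, mean, numeric(1)),
                    sd = if (nrow(anthro) > 1L)
                      vapply(num, stats::sd, numeric(1)) else NA_real_,
                    row.names = NULL)
  if (!is.null(round_digits)) {
    idx <- match(out$variable, names(round_digits))
    dg <- ifelse(is.na(idx), 2L, round_digits[idx])
    out$mean <- round(out$mean, dg)
    out$sd <- round(out$sd, dg)
  }
  out
}

#' Fit the linear neck-length predictor
#'
#' Ordinary least squares of the identified neck-stick length on the
#' palpable C2-C7 distance: `l12 = beta1 * lC2C7 + beta0`. Both variables
#' are handled in meters internally; `lC2C7` may be supplied in centimeters
#' (the palpation convention, default) or meters.
#'
#' @param lC2C7 numeric vector of palpated C2-C7 lengths.
#' @param l12 numeric vector of identified neck-stick lengths, meters.
#' @param units units of `lC2C7`: `"cm"` (default) or `"m"`.
#' @return an object of class `length_model`: list with `beta0` (meters),
#'   `beta1` (dimensionless), `residual_sd` (meters, n-2 denominator; 0 when
#'   n == 2), and the underlying `lm` fit as attribute `"fit"`.
#' @export
fit_length_model <- function(lC2C7, l12, units = c("cm", "m")) {
  units <- match.arg(units)
  x <- if (units == "cm") lC2C7 / 100 else lC2C7
  y <- as.numeric(l12)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (max(x) - min(x) < 1e-12)
    ns_stop("neckstick_degenerate_predictor",
            "all C2-C7 lengths are equal; the slope is unidentifiable")
  fit <- stats::lm(y ~ x)
  res_sd <- if (length(x) > 2L) sqrt(sum(stats::residuals(fit)^2) / (length(x) - 2))
            else 0
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 residual_sd = res_sd),
            class = "length_model", fit = fit)
}

#' @export
print.length_model <- function(x, ...) {
  cat(sprintf("<length_model> l12 = %.4f * lC2C7 + %.4f m  (residual SD %.2f mm)\n",
              x$beta1, x$beta0, m_to_mm(x$residual_sd)))
  invisible(x)
}

#' Predict the neck-stick length from the palpable C2-C7 distance
#'
#' @param model a [fit_length_model()] result.
#' @param lC2C7 palpated C2-C7 length.
#' @param units units of `lC2C7`: `"cm"` (default) or `"m"`.
#' @return predicted neck-stick length, meters. A non-positive prediction is
#'   an error (nonphysical).
#' @export
predict_l12 <- function(model, lC2C7, units = c("cm", "m")) {
  units <- match.arg(units)
  stopifnot(inherits(model, "length_model"), all(lC2C7 > 0))
  x <- if (units == "cm") lC2C7 / 100 else lC2C7
  out <- model$beta1 * x + model$beta0
  if (any(out <= 0))
    ns_stop("neckstick_nonphysical",
            "predicted neck length is non-positive (%.4f m) - outside the model's domain",
            min(out))
  out
}

#' Residuals of the parametrized model against the fitted model
#'
#' Replaces the individually fitted neck-stick length by its anthropometric
#' prediction (thorax vector unchanged) and summarizes, per axis, the
#' displacement of the J2 (head-center) trajectory relative to the fitted
#' model's J2 trajectory. Because J2 is linear in the stick length, each
#' per-sample difference is `(predicted_l12 - fitted_l12)` along the
#' instantaneous stick direction.
#'
#' @param recordings calibrated [trial_recording()] or list of them (one
#'   participant).
#' @param predicted_l12 anthropometric length prediction, meters.
#' @param reference_fit the participant's [fit_parameters()] result.
#' @return data.frame from [residual_stats()] (columns `axis`, `me_mm`,
#'   `p5_mm`, `p95_mm`), parametrized minus fitted.
#' @export
evaluate_parametrized_model <- function(recordings, predicted_l12,
                                        reference_fit) {
  if (!inherits(reference_fit, "neck_fit"))
    ns_stop("neckstick_missing_reference",
            "reference_fit must be a neck_fit for the same participant")
  if (inherits(recordings, "trial_recording")) recordings <- list(recordings)
  pf <- reference_fit$params
  pp <- neck_parameters(l12 = predicted_l12, vs1 = pf$vs1, v2h = pf$v2h)
  fitted_j2 <- do.call(rbind, lapply(recordings, function(r) j2_series(pf, r)))
  param_j2 <- do.call(rbind, lapply(recordings, function(r) j2_series(pp, r)))
  residual_stats(param_j2, fitted_j2)
}
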