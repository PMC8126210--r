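# End-to-end pipeline: simulate (or load) a cohort, calibrate, fit each
# participant, fit the anthropometric length model across participants,
# validate the parametrized model, optionally run the noise sweep, and
# write all artifacts with full seed provenance.

#' Run the full analysis pipeline
#'
#' Stages (mirroring the study workflow): per participant, calibrate the
#' trials on the static lead-in and identify the seven model parameters by
#' pooled linear least squares; across participants, fit the linear length
#' law `l12 ~ lC2C7`; per participant, evaluate the parametrized model
#' (anthropometrically predicted length) against the fitted model; and
#' optionally run the Monte-Carlo noise sweep on the first participant.
#'
#' Artifacts written to `out_dir`: `params_<id>.json`, `residuals_fitted.csv`
#' (per-participant ME / 5% / 95% per axis of the fitted model),
#' `residuals_parametrized.csv` (same layout for the parametrized model's J2
#' trajectory vs the fitted one), `length_model.json`, optionally
#' `noise_sweep.csv` + `noise_sweep_summary.csv`, and `run_log.txt` with
#' versions, seeds and settings. All stochastic stages derive their seeds
#' from the single master `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort a [generate_cohort()] result, or `NULL` to generate
#'   `n_subjects` participants from `seed`.
#' @param n_subjects cohort size when `cohort` is `NULL`.
#' @param seed master seed.
#' @param tasks task battery, default [standard_tasks()].
#' @param marker_noise_sd simulated marker noise SD, meters.
#' @param sample_rate sampling rate, Hz.
#' @param noise_sweep logical: run [run_noise_sweep()] on participant 1.
#' @param sweep_args list of extra arguments for [run_noise_sweep()].
#' @param keep_recordings logical: return the simulated recordings too.
#' @return invisibly, a list with `fits`, `length_model`,
#'   `residuals_fitted`, `residuals_parametrized`, `sweep` (or `NULL`),
#'   `paths`, and optionally `recordings`.
#' @export
run_pipeline <- function(out_dir,
                         cohort = NULL,
                         n_subjects = 4L,
                         seed = 1L,
                         tasks = standard_tasks(),
                         marker_noise_sd = 1e-4,
                         sample_rate = 120,
                         noise_sweep = FALSE,
                         sweep_args = list(),
                         keep_recordings = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) cohort <- generate_cohort(n_subjects, seed = derive_seed(seed, 0L))
  log_lines <- c(sprintf("neckstick %s | R %s",
                         as.character(utils::packageVersion("neckstick")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("master seed: %d", as.integer(seed)),
                 sprintf("subjects: %d | tasks: %s", length(cohort),
                         paste(names(tasks), collapse = ", ")),
                 sprintf("marker noise SD: %g m | sample rate: %g Hz",
                         marker_noise_sd, sample_rate),
                 "rank tolerance: max singular value x 1e-10",
                 "percentiles: linear interpolation (type 7)")

  fits <- list(); recs_all <- list()
  res_fitted <- list(); res_param <- list()
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    recs <- simulate_participant(p, tasks = tasks, seed = derive_seed(seed, i),
                                 marker_noise_sd = marker_noise_sd,
                                 sample_rate = sample_rate)
    fit <- fit_parameters(recs)
    fits[[p$id]] <- fit
    res_fitted[[p$id]] <- fit$per_axis_residuals
    recs_all[[p$id]] <- recs  # needed for the parametrized-model stage
    write_params_json(fit, file.path(out_dir, sprintf("params_%s.json", p$id)))
    log_lines <- c(log_lines,
                   sprintf("participant %s: seed %d, %d samples, l12 %.2f mm (truth %.2f mm)",
                           p$id, derive_seed(seed, i), fit$n_samples,
                           m_to_mm(fit$params$l12), m_to_mm(p$params$l12)))
  }
  utils::write.csv(residual_table(res_fitted),
                   file.path(out_dir, "residuals_fitted.csv"), row.names = FALSE)

  lC2C7 <- vapply(cohort, function(p) p$anthro$length_C2C7_cm, numeric(1))
  l12_hat <- vapply(fits, function(f) f$params$l12, numeric(1))
  lmod <- fit_length_model(lC2C7, l12_hat, units = "cm")
  jsonlite::write_json(list(beta0_m = lmod$beta0, beta1 = lmod$beta1,
                            residual_sd_m = lmod$residual_sd),
                       file.path(out_dir, "length_model.json"),
                       auto_unbox = TRUE, digits = NA)

  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    res_param[[p$id]] <- evaluate_parametrized_model(
      recs_all[[p$id]], predict_l12(lmod, lC2C7[i]), fits[[p$id]])
  }
  utils::write.csv(residual_table(res_param),
                   file.path(out_dir, "residuals_parametrized.csv"),
                   row.names = FALSE)

  sweep <- NULL
  if (noise_sweep) {
    sweep <- do.call(run_noise_sweep,
                     c(list(recordings = recs_all[[1]],
                            seed = derive_seed(seed, 1000L)),
                       sweep_args))
    utils::write.csv(sweep, file.path(out_dir, "noise_sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(summarize_sweep(sweep),
                     file.path(out_dir, "noise_sweep_summary.csv"),
                     row.names = FALSE)
    log_lines <- c(log_lines, sprintf("noise sweep seed: %d", derive_seed(seed, 1000L)))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  out <- list(fits = fits, length_model = lmod,
              residuals_fitted = residual_table(res_fitted),
              residuals_parametrized = residual_table(res_param),
              sweep = sweep,
              paths = list.files(out_dir, full.names = TRUE))
  if (keep_recordings) out$recordings <- recs_all
  invisible(out)
}
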