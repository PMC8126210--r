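# Plain-text trial I/O. Marker trajectory tables are comma-separated with a
# header row: time_s, then <body>_<marker#>_<x|y|z> in millimeters, bodies
# head / sternum / neck, three markers each (120 Hz default rate). All
# column names declare their units (seconds, millimeters).

marker_columns <- function() {
  unlist(lapply(NS_BODIES, function(b)
    unlist(lapply(1:3, function(k)
      paste(b, k, c("x", "y", "z"), sep = "_")))))
}

#' Write a trial recording to a marker trajectory CSV
#'
#' Columns: `time_s`, then `<body>_<marker#>_<x|y|z>` in millimeters.
#'
#' @param recording a [trial_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(recording, path) {
  df <- data.frame(time_s = recording$time)
  for (b in NS_BODIES) {
    M <- m_to_mm(recording$markers[[b]])
    colnames(M) <- paste(b, rep(1:3, each = 3), c("x", "y", "z"), sep = "_")
    df <- cbind(df, M)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a marker trajectory CSV into a trial recording
#'
#' Validates the header (all 27 marker columns present), strictly monotone
#' timestamps, and the absence of non-finite cells; marker columns are
#' converted from millimeters to meters and body poses are derived per
#' sample.
#'
#' @param path input file path.
#' @param geometry tripod reference geometry used for pose derivation.
#' @return a [trial_recording()].
#' @export
read_trial <- function(path, geometry = tripod_geometry()) {
  if (!file.exists(path))
    ns_stop("neckstick_parse_error", "trial file '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_s", marker_columns())
  missing <- setdiff(needed, names(df))
  if (length(missing))
    ns_stop("neckstick_parse_error", "trial file '%s' lacks column(s): %s",
            path, paste(missing, collapse = ", "))
  bad <- which(!stats::complete.cases(df[needed]) |
                 apply(!sapply(df[needed], is.finite), 1, any))
  if (length(bad))
    ns_stop("neckstick_parse_error",
            "trial file '%s' has non-finite cells at data line(s): %s",
            path, paste(utils::head(bad, 5), collapse = ", "))
  if (any(diff(df$time_s) <= 0))
    ns_stop("neckstick_nonmonotone_time",
            "trial file '%s': time_s is not strictly increasing (first violation at data line %d)",
            path, which(diff(df$time_s) <= 0)[1] + 1L)
  markers <- list()
  for (b in NS_BODIES) {
    cols <- paste(b, rep(1:3, each = 3), c("x", "y", "z"), sep = "_")
    markers[[b]] <- unname(mm_to_m(as.matrix(df[cols])))
  }
  trial_recording(df$time_s, markers, geometry = geometry)
}

#' Write fitted parameters to JSON
#'
#' Layout: `{l12_mm, vs1_mm: [...], v2h_mm: [...]}` plus fit metadata.
#'
#' @param fit a [fit_parameters()] result (or bare [neck_parameters()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(fit, path) {
  params <- if (inherits(fit, "neck_fit")) fit$params else fit
  payload <- list(l12_mm = m_to_mm(params$l12),
                  vs1_mm = m_to_mm(params$vs1),
                  v2h_mm = m_to_mm(params$v2h))
  if (inherits(fit, "neck_fit"))
    payload <- c(payload, list(n_samples = fit$n_samples,
                               condition_number = fit$condition_number))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Residual-summary table in wide per-participant layout
#'
#' One row per participant; columns `me_x_mm`, `p5_x_mm`, `p95_x_mm`, then
#' the same for y and z (mean error and 5%/95% percentiles per axis, mm,
#' rounded to 2 decimals).
#'
#' @param summaries named list of [residual_stats()] data.frames, one per
#'   participant.
#' @return data.frame with a leading `participant` column.
#' @export
residual_table <- function(summaries) {
  rows <- lapply(names(summaries), function(id) {
    s <- summaries[[id]]
    vals <- round(c(rbind(s$me_mm, s$p5_mm, s$p95_mm)), 2)
    names(vals) <- as.vector(outer(c("me", "p5", "p95"), s$axis,
                                   function(a, b) paste0(a, "_", b, "_mm")))
    cbind(data.frame(participant = id), as.data.frame(as.list(vals)))
  })
  do.call(rbind, rows)
}
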