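# Internal helpers: classed conditions, unit conversion, seed fan-out.

ns_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "neckstick_error")))
}

ns_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = c(class, "neckstick_warning")))
}

m_to_mm <- function(x) x * 1000
mm_to_m <- function(x) x / 1000
deg_to_rad <- function(x) x * pi / 180
rad_to_deg <- function(x) x * 180 / pi

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage / per-repetition
#' seeds, so that a single `--seed` reproduces every stochastic stage of a
#' run. The result is always a valid positive 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L)
  # affine hop in a Mersenne-prime field keeps streams distinct and in range
  m <- 2147483647
  x <- ((abs(master) %% m) * 48271) %% m        # exact: < 2^53 in double
  as.integer((x + (index * 104729) %% m) %% m) + 1L
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
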