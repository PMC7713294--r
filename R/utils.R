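# Internal helpers: classed conditions, seeded evaluation, small checks.

abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "carokin_error")))
}

warn <- function(message, class = "carokin_warning") {
  warning(warningCondition(message, class = c(class, "carokin_warning")))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the previous RNG state, so
#' seeded routines (the particle swarm, the noise generator) never disturb
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_preserved_seed <- function(seed, code) {
  if (!is_count(seed, min = 0L)) {
    abort("`seed` must be a single non-negative integer",
          "carokin_invalid_input")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# minutes <-> seconds; all solver-facing times are seconds
min_to_s <- function(x) x * 60
s_to_min <- function(x) x / 60

# Write `lines`/data.frame to `path` atomically (temp file + rename).
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(sprintf("could not write '%s'", path), "carokin_io_error")
  }
  ok <- TRUE
  invisible(path)
}
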