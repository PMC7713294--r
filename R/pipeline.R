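# Pipeline driver: JSON config -> synthetic data / CSV data -> fit ->
# pattern summaries, with reproducible logging and atomic artifact writes.

config_schema <- function() {
  list(
    seed = NULL, output_dir = NULL, verbosity = NULL,
    network = c("n_steps", "extended", "branches"),
    data = c("source", "scenario", "files", "assay", "noise"),
    fit = c("iterations", "swarm_size", "weighting", "bounds", "inertia",
            "cognitive", "social", "log_kcat", "sim_rtol", "sim_atol"),
    pattern = c("detection_limit", "at_time_min"),
    simulate = c("rtol", "atol")
  )
}

validate_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s) at top level: %s",
                  paste(unknown, collapse = ", ")), "carokin_config_error")
  }
  for (key in names(config)) {
    allowed <- schema[[key]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[key]]), allowed)
    if (length(bad)) {
      abort(sprintf("unknown config key(s) under '%s': %s", key,
                    paste(bad, collapse = ", ")), "carokin_config_error")
    }
  }
  if (is.null(config$output_dir)) {
    abort("config needs 'output_dir'", "carokin_config_error")
  }
  invisible(config)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

assay_from_config <- function(x) {
  if (is.character(x) && length(x) == 1L) return(preset_assay(x))
  if (inherits(x, "assay_spec")) return(x)
  do.call(assay_spec, as.list(x))
}

#' Run the modelling pipeline
#'
#' Drives simulate/synth -> fit -> pattern from a single configuration
#' (a JSON file path or an equivalent list; see `read_run_config()`).
#' Unknown configuration keys are rejected with their location. Artifacts
#' (time-course CSVs, fit JSON, pattern CSVs, a log recording the seed,
#' bounds, tolerances and package version) are written atomically into
#' `output_dir`; partial outputs are removed on failure.
#'
#' @param config Path to a JSON config or a config list.
#' @return Invisibly, a list with `status` (0 on success) and `artifacts`
#'   (named file paths).
#' @examples
#' \dontrun{
#' run_pipeline(list(
#'   seed = 1, output_dir = tempdir(),
#'   data = list(source = "synthetic", scenario = "fast_archetype"),
#'   fit = list(iterations = 50, swarm_size = 10)
#' ))
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  } else {
    validate_config(config)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  failed <- TRUE
  on.exit(if (failed) unlink(artifacts), add = TRUE)

  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  logline <- character(0)
  say <- function(fmt, ...) {
    logline <<- c(logline, sprintf(fmt, ...))
    if (!identical(config$verbosity, "quiet")) message(sprintf(fmt, ...))
  }
  say("carokin %s pipeline run", as.character(packageVersion("carokin")))
  say("seed: %d", seed)

  # --- network ---------------------------------------------------------
  netcfg <- config$network
  network <- build_network(
    n_steps = if (is.null(netcfg$n_steps)) 4 else netcfg$n_steps,
    extended = isTRUE(netcfg$extended),
    branch_spec = netcfg$branches
  )
  say("network: %d-step chain, %d branches", network$n_steps,
      nrow(network$branches))

  # --- data ------------------------------------------------------------
  datacfg <- config$data
  if (is.null(datacfg)) {
    abort("config needs a 'data' section", "carokin_config_error")
  }
  experiments <- list()
  if (identical(datacfg$source, "synthetic")) {
    ns <- if (is.null(datacfg$noise)) {
      noise_spec(cv = 0, floor = 0, seed = seed)
    } else {
      do.call(noise_spec, modifyList(as.list(datacfg$noise),
                                     list(seed = seed)))
    }
    sc <- scenario_preset(datacfg$scenario, noise = ns)
    tc <- generate_timecourse(sc)
    p <- file.path(config$output_dir,
                   sprintf("timecourse_%s.csv", sc$label))
    write_timecourse(tc, p)
    sidecar <- file.path(config$output_dir,
                         sprintf("timecourse_%s_truth.json", sc$label))
    write_atomic(function(pp) jsonlite::write_json(
      list(scenario = sc$label, seed = seed,
           true_params = unclass(sc$true_params)),
      pp, auto_unbox = TRUE, digits = NA), sidecar)
    artifacts <- c(artifacts, timecourse = p, truth = sidecar)
    experiments <- list(list(assay = sc$assay, timecourse = tc))
    network <- sc$network
    say("synthetic scenario: %s (cv %.3g, floor %.3g)", sc$label, ns$cv,
        ns$floor)
  } else if (identical(datacfg$source, "csv")) {
    assay <- assay_from_config(datacfg$assay)
    experiments <- lapply(datacfg$files, function(f) {
      list(assay = assay, timecourse = read_timecourse(f))
    })
    say("loaded %d time course(s) from CSV", length(experiments))
  } else {
    abort("config data$source must be 'synthetic' or 'csv'",
          "carokin_config_error")
  }

  # --- fit -------------------------------------------------------------
  fit <- NULL
  if (!is.null(config$fit)) {
    fitcfg <- do.call(fit_config,
                      c(list(network = network, seed = seed),
                        config$fit[setdiff(names(config$fit), "bounds")]))
    say("fit: %d iterations, swarm %d, weighting %s, sim_rtol %g",
        fitcfg$iterations, fitcfg$swarm_size, fitcfg$weighting,
        fitcfg$sim_rtol)
    say("bounds: k_f [%g, %g] k_r [%g, %g] k_cat [%g, %g]",
        fitcfg$bounds$lower[1], fitcfg$bounds$upper[1],
        fitcfg$bounds$lower[network$n_steps + 2],
        fitcfg$bounds$upper[network$n_steps + 2],
        min(fitcfg$bounds$lower), max(fitcfg$bounds$upper))
    fit <- fit_pso(network, experiments, fitcfg)
    p <- file.path(config$output_dir, "fit_result.json")
    write_fit_result(fit, p)
    artifacts <- c(artifacts, fit = p)
    say("fit objective: %.8g", fit$objective_value)
  }

  # --- pattern ---------------------------------------------------------
  if (!is.null(config$pattern)) {
    limit <- if (is.null(config$pattern$detection_limit)) 0.01 else
      config$pattern$detection_limit
    tc <- experiments[[1]]$timecourse
    at <- if (is.null(config$pattern$at_time_min)) max(tc$time_min) else
      config$pattern$at_time_min
    row <- which.min(abs(tc$time_min - at))
    conc <- unlist(tc[row, timecourse_species(tc)])
    # reporting-time censoring: anything below the detection limit
    # (including sub-tolerance solver residues) reads as absent
    conc[conc < limit] <- 0
    ps <- pattern_summary(conc, detection_limit = limit)
    p <- file.path(config$output_dir, "pattern_summary.csv")
    write_pattern_summary(ps, p)
    artifacts <- c(artifacts, pattern = p,
                   pattern_grid = sub("\\.csv$", "_grid.csv", p))
    say("pattern summary at %g min (detection limit %g µM)", at, limit)
  }

  logp <- file.path(config$output_dir, "run.log")
  write_atomic(function(p) writeLines(logline, p), logp)
  artifacts <- c(artifacts, log = logp)
  failed <- FALSE
  invisible(list(status = 0L, artifacts = artifacts))
}

#' Serialise a fit result to JSON
#'
#' Includes the seed, bounds, best parameters, derived constants and the
#' optimizer trace; contains no timestamps, so identical runs produce
#' byte-identical files.
#'
#' @param fit A `fit_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  payload <- list(
    seed = fit$seed,
    iterations = fit$config$iterations,
    swarm_size = fit$config$swarm_size,
    weighting = fit$config$weighting,
    sim_rtol = fit$config$sim_rtol,
    sim_atol = fit$config$sim_atol,
    bounds = fit$config$bounds,
    best_params = unclass(fit$best_params),
    objective_value = fit$objective_value,
    derived_constants = fit$derived_constants,
    trace = fit$trace,
    n_failed_evals = fit$n_failed_evals
  )
  write_atomic(function(p) jsonlite::write_json(payload, p, auto_unbox = TRUE,
                                                digits = NA, na = "null"),
               path)
}

#' Read back a serialised fit result
#' @param path JSON file written by [write_fit_result()].
#' @return A list (not a full `fit_result`).
#' @export
read_fit_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `fit`, `synth`, `pattern`, `recover`. All are
#' thin wrappers over [run_pipeline()] and [recovery_suite()]; a config
#' file (`--config`) provides the settings, flags override `seed` and
#' `output_dir`. Installed as `inst/cli/carokin.R`, runnable via
#' `Rscript $(Rscript -e 'cat(system.file("cli/carokin.R", package="carokin"))') ...`
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status, invisibly (0 on success).
#' @export
carokin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: carokin <simulate|fit|synth|pattern|recover> --config <json>",
    "[--seed <int>] [--out <dir>] [--draws <int>]")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opts[[key]] <- if (i + 1L <= length(args)) args[i + 1L] else NA
    i <- i + 2L
  }
  status <- tryCatch({
    cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else list()
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) cfg$output_dir <- opts$out
    switch(cmd,
      synth = ,
      simulate = {
        cfg$fit <- NULL
        run_pipeline(cfg)$status
      },
      fit = run_pipeline(cfg)$status,
      pattern = {
        cfg$fit <- NULL
        if (is.null(cfg$pattern)) cfg$pattern <- list(detection_limit = 0.01)
        run_pipeline(cfg)$status
      },
      recover = {
        draws <- if (is.null(opts$draws)) 1L else as.integer(opts$draws)
        seed <- if (is.null(cfg$seed)) 1L else cfg$seed
        network <- build_network(4)
        fc <- do.call(fit_config, c(list(network = network, seed = seed),
                                    cfg$fit[setdiff(names(cfg$fit), "bounds")]))
        rep <- recovery_suite(draws, seed, fc, network)
        dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
        p <- file.path(cfg$output_dir, "recovery_report.csv")
        write_atomic(function(pp) write.csv(rep$errors, pp, row.names = FALSE), p)
        print(rep)
        0L
      },
      { message(usage); 1L }
    )
  }, error = function(e) {
    message("carokin error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
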