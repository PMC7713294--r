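#' Simulate a desaturation assay
#'
#' Integrates the mass-action ODE system over the assay window with the
#' built-in stiff SDIRK3(2) solver and reports observable species totals at
#' the sampling times. The observable for each carotene is free plus
#' enzyme-bound concentration: the chloroform/methanol quench denatures the
#' enzyme and releases bound carotenes, so HPLC sees the sum. Rate
#' constants span four orders of magnitude, hence the tight default
#' tolerances (`rtol = 1e-8`, `atol = 1e-10` µM); negative-concentration
#' clipping is never applied.
#'
#' @param network A `crti_network`.
#' @param params A matching `kinetic_params` object.
#' @param assay An [assay_spec()].
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param full_state Attach the full state matrix (free species, free
#'   enzyme, complexes) as attribute `"state"`.
#' @param max_steps Step-count guard for the integrator.
#' @return A `crti_timecourse`: a data.frame with `time_min` and one column
#'   per observable species (µM), with a `metadata` attribute recording the
#'   assay and solver settings. The first row equals the initial condition
#'   exactly.
#' @examples
#' net <- build_network(4)
#' p <- kinetic_parameters(rep(0.5, 5), rep(5, 5), c(0.02, 0.02, 0.015, 0.01))
#' tc <- simulate_timecourse(net, p, preset_assay("dense_schedule"))
#' peak_times(tc)
#' @export
simulate_timecourse <- function(network, params, assay,
                                rtol = 1e-8, atol = 1e-10,
                                full_state = FALSE, max_steps = 5e5) {
  stopifnot(inherits(network, "crti_network"), inherits(assay, "assay_spec"))
  check_state_params(initial_state(network, assay), params, network)
  y0 <- initial_state(network, assay)
  times_s <- min_to_s(assay$sampling_times)
  a <- network_cpp_args(network, assay$phytoene_influx)
  sol <- crti_integrate_cpp(as.numeric(y0), times_s, a$n_steps,
                            params$k_f, params$k_r, params$k_cat,
                            a$bsrc, a$bdst, a$bvmax, a$bkm, a$influx,
                            a$n_branch_species, rtol, atol, max_steps)
  if (sol$status != 0) {
    abort(sprintf("integration failed: %s (t reached output %d of %d, %d steps)",
                  sol$message, sol$n_out, length(times_s), sol$steps),
          "carokin_integration_error")
  }
  states <- sol$states
  colnames(states) <- network$state_names
  totals <- observable_totals(states, network)
  out <- data.frame(time_min = assay$sampling_times, totals,
                    check.names = FALSE)
  attr(out, "metadata") <- list(
    assay = assay, enzyme = network$enzyme, rtol = rtol, atol = atol,
    steps = sol$steps, nfev = sol$nfev
  )
  if (full_state) attr(out, "state") <- states
  class(out) <- c("crti_timecourse", "data.frame")
  out
}

observable_totals <- function(states, network) {
  n <- network$n_steps
  chain <- states[, seq_len(n + 1L), drop = FALSE] +
    states[, (n + 3L):(2L * n + 3L), drop = FALSE]
  colnames(chain) <- network$chain
  extra <- ncol(states) - (2L * n + 3L)
  if (extra > 0) {
    branch <- states[, (2L * n + 4L):ncol(states), drop = FALSE]
    cbind(chain, branch)
  } else {
    chain
  }
}

#' Observable species of a time course
#' @param tc A `crti_timecourse`.
#' @return Character vector of species column names.
#' @export
timecourse_species <- function(tc) setdiff(names(tc), "time_min")

#' Apply an HPLC detection limit to a time course
#'
#' Sets entries below the limit to zero. This mirrors HPLC reporting and is
#' deliberately separate from integration: the solver never clips.
#'
#' @param tc A `crti_timecourse`.
#' @param limit Detection limit in µM; defaults to the assay's.
#' @return The censored time course.
#' @export
apply_detection_limit <- function(tc, limit = NULL) {
  md <- attr(tc, "metadata")
  if (is.null(limit)) limit <- md$assay$detection_limit
  for (s in timecourse_species(tc)) tc[[s]][tc[[s]] < limit] <- 0
  tc
}

#' Time of maximum for every species
#'
#' The sampling time (minutes) at which each observable total is maximal;
#' ties resolve to the earliest time. In the fast-enzyme regime the early
#' intermediates (phytofluene, zeta-carotene, neurosporene) peak well
#' before the terminal product plateaus.
#'
#' @param tc A `crti_timecourse`.
#' @return Named numeric vector of peak times (minutes).
#' @export
peak_times <- function(tc) {
  sp <- timecourse_species(tc)
  if (nrow(tc) < 1L || length(sp) < 1L) {
    abort("empty time course", "carokin_invalid_input")
  }
  vapply(setNames(sp, sp), function(s) tc$time_min[which.max(tc[[s]])],
         numeric(1))
}

#' Quasi-steady-state initial rate of a catalytic step
#'
#' The Michaelis-Menten initial rate `k_cat E_total S0 / (K_m + S0)` with
#' `K_m = (k_r + k_cat) / k_f`; the closed-form limit the full ODE system
#' approaches when total enzyme is catalytic (`E_total << S0 + K_m`).
#'
#' @param params A `kinetic_params` object.
#' @param S0 Substrate concentration, µM (> 0).
#' @param E_total Total enzyme, µM (> 0).
#' @param step Catalytic step index (1-based, <= number of steps).
#' @return Rate in µM/s.
#' @export
initial_rate_qss <- function(params, S0, E_total, step = 1L) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is_count(step) || step > length(params$k_cat)) {
    abort(sprintf("step %s has no catalytic reaction", format(step)),
          "carokin_unknown_step")
  }
  if (!is_number(S0) || S0 <= 0 || !is_number(E_total) || E_total <= 0) {
    abort("S0 and E_total must be > 0", "carokin_domain_error")
  }
  km <- (params$k_r[step] + params$k_cat[step]) / params$k_f[step]
  params$k_cat[step] * E_total * S0 / (km + S0)
}

#' Write a time course to CSV
#'
#' Header `time_min,<species...>`, one row per sampling time, values in µM
#' written with enough digits to round-trip losslessly at 6 significant
#' digits.
#'
#' @param tc A `crti_timecourse` (or plain data.frame with `time_min`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  df <- as.data.frame(tc)
  for (col in names(df)) df[[col]] <- formatC(df[[col]], format = "g", digits = 9)
  write_atomic(function(p) write.csv(df, p, row.names = FALSE, quote = FALSE),
               path)
}

#' Read a time course CSV
#'
#' @param path CSV with header `time_min,<species...>`.
#' @return A `crti_timecourse` data.frame.
#' @export
read_timecourse <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_min") {
    abort(sprintf("first column must be 'time_min', found '%s'", names(df)[1]),
          "carokin_format_error")
  }
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) {
      abort(sprintf("column '%s' is not numeric", col), "carokin_format_error")
    }
  }
  known <- carotene_species()$name
  bad <- setdiff(names(df)[-1], known)
  if (length(bad)) {
    abort(sprintf("unknown species column: %s", paste(bad, collapse = ", ")),
          "carokin_format_error")
  }
  class(df) <- c("crti_timecourse", "data.frame")
  df
}
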