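#' Initial state of an assay
#'
#' All carotene starts as free phytoene and all enzyme free; complexes and
#' downstream species are zero.
#'
#' @param network A `crti_network`.
#' @param assay An [assay_spec()].
#' @return Named numeric vector over `network$state_names` (µM).
#' @export
initial_state <- function(network, assay) {
  stopifnot(inherits(network, "crti_network"), inherits(assay, "assay_spec"))
  y <- setNames(numeric(length(network$state_names)), network$state_names)
  y["phytoene"] <- assay$initial_phytoene
  y["E"] <- assay$enzyme_total
  y
}

#' Mass-action right-hand side of the desaturation ODE system
#'
#' Time derivatives (µM/s) of every state entry under mass-action kinetics:
#' `d[ES_i]/dt = k_f[i] E S_i - (k_r[i] + k_cat[i]) ES_i` (no `k_cat` for
#' the terminal dead-end complex), with the free-species and free-enzyme
#' equations closing the carotene-backbone and enzyme conservation laws
#' exactly. Cyclisation branches contribute irreversible Michaelis-Menten
#' fluxes on free species; `influx` is a zeroth-order phytoene source.
#'
#' @param state Named (or positional) numeric state vector over
#'   `network$state_names`, all entries >= 0, in µM.
#' @param params A `kinetic_params` object matching the network.
#' @param network A `crti_network`.
#' @param influx Zeroth-order phytoene source, µM/s (default 0).
#' @return Numeric derivative vector, same names as the state.
#' @export
network_rhs <- function(state, params, network, influx = 0) {
  stopifnot(inherits(network, "crti_network"))
  check_state_params(state, params, network)
  if (any(state < 0)) {
    abort("state concentrations must be >= 0", "carokin_domain_error")
  }
  a <- network_cpp_args(network, influx)
  dy <- crti_rhs_cpp(as.numeric(state), a$n_steps, params$k_f, params$k_r,
                     params$k_cat, a$bsrc, a$bdst, a$bvmax, a$bkm, a$influx,
                     a$n_branch_species)
  setNames(dy, network$state_names)
}

check_state_params <- function(state, params, network) {
  if (length(state) != length(network$state_names)) {
    abort(sprintf("state has length %d; network needs %d entries",
                  length(state), length(network$state_names)),
          "carokin_shape_error")
  }
  if (!inherits(params, "kinetic_params") ||
      length(params$k_cat) != network$n_steps) {
    abort("parameter dimensions do not match the network",
          "carokin_shape_error")
  }
  invisible(TRUE)
}

#' Conservation drift of a simulated trajectory
#'
#' The network conserves two linear quantities: the carotene backbone count
#' (free chain and branch species plus enzyme-bound complexes) and the
#' total enzyme (free plus complexed) -- unless a phytoene influx feeds the
#' system. This reports the maximum relative drift of both totals over a
#' trajectory, the package's primary integration-quality diagnostic.
#'
#' @param trajectory Numeric matrix of full states (rows = time points,
#'   columns = `network$state_names`), e.g. the `"state"` attribute of a
#'   [simulate_timecourse()] call with `full_state = TRUE`.
#' @param network The `crti_network` the trajectory belongs to.
#' @return Named numeric vector `c(carotene = ..., enzyme = ...)` of
#'   maximum `|total(t) - total(0)| / total(0)`.
#' @export
conservation_residuals <- function(trajectory, network) {
  stopifnot(inherits(network, "crti_network"))
  traj <- as.matrix(trajectory)
  if (nrow(traj) < 1L || ncol(traj) != length(network$state_names)) {
    abort("trajectory must be a non-empty matrix over the network state",
          "carokin_shape_error")
  }
  n <- network$n_steps
  carotene_cols <- setdiff(seq_along(network$state_names), n + 2L)
  enzyme_cols <- (n + 2L):(2L * n + 3L)
  drift <- function(cols) {
    tot <- rowSums(traj[, cols, drop = FALSE])
    if (tot[1] <= 0) {
      abort("initial conserved total is zero; relative drift undefined",
            "carokin_undefined_ratio")
    }
    max(abs(tot - tot[1]) / tot[1])
  }
  c(carotene = drift(carotene_cols), enzyme = drift(enzyme_cols))
}
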