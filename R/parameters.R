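#' Kinetic rate constants for a desaturation network
#'
#' Bundles the per-complex binding (`k_f`, µM^-1 s^-1), unbinding
#' (`k_r`, s^-1) and per-step catalytic (`k_cat`, s^-1) rate constants.
#' A network with `n` catalytic steps has `n + 1` binding equilibria (one
#' per chain species, terminal product included) and `n` catalytic steps,
#' i.e. `3n + 2` free parameters (14 for the default 4-step chain).
#'
#' @param k_f Numeric vector of binding rate constants, length `n + 1`.
#' @param k_r Numeric vector of unbinding rate constants, length `n + 1`.
#' @param k_cat Numeric vector of catalytic rate constants, length `n`.
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_parameters(k_f = rep(0.5, 5), k_r = rep(5, 5),
#'                         k_cat = c(0.02, 0.02, 0.015, 0.01))
#' derive_constants(p)
#' @export
kinetic_parameters <- function(k_f, k_r, k_cat) {
  if (!is.numeric(k_f) || !is.numeric(k_r) || !is.numeric(k_cat)) {
    abort("rate constants must be numeric", "carokin_invalid_input")
  }
  if (length(k_f) != length(k_r) || length(k_f) != length(k_cat) + 1L ||
      length(k_cat) < 1L) {
    abort(paste("length mismatch: need length(k_f) == length(k_r) ==",
                "length(k_cat) + 1"), "carokin_shape_error")
  }
  if (any(!is.finite(c(k_f, k_r, k_cat))) || any(c(k_f, k_r, k_cat) < 0)) {
    abort("rate constants must be finite and >= 0", "carokin_domain_error")
  }
  structure(list(k_f = as.numeric(k_f), k_r = as.numeric(k_r),
                 k_cat = as.numeric(k_cat)),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  n <- length(x$k_cat)
  cat(sprintf("Kinetic parameters for a %d-step desaturation chain\n", n))
  cat("  k_f   (µM^-1 s^-1):", format(x$k_f, digits = 4), "\n")
  cat("  k_r   (s^-1)      :", format(x$k_r, digits = 4), "\n")
  cat("  k_cat (s^-1)      :", format(x$k_cat, digits = 4), "\n")
  invisible(x)
}

#' Default fitting bounds for the rate constants
#'
#' The bounds used for parameter estimation: `k_f` in \[0.1, 1\]
#' µM^-1 s^-1, `k_r` in \[1, 10\] s^-1 and `k_cat` in \[1e-5, 0.1\] s^-1.
#' At the binding-bound extremes the derived dissociation constants
#' `K_d = k_r / k_f` span 1 to 100 µM.
#'
#' @param network A `crti_network` (determines the number of parameters).
#' @return A data.frame with columns `parameter`, `lower`, `upper`.
#' @export
default_parameter_bounds <- function(network = build_network(4)) {
  stopifnot(inherits(network, "crti_network"))
  n <- network$n_steps
  data.frame(
    parameter = parameter_names(network),
    lower = c(rep(0.1, n + 1L), rep(1, n + 1L), rep(1e-5, n)),
    upper = c(rep(1, n + 1L), rep(10, n + 1L), rep(0.1, n)),
    stringsAsFactors = FALSE
  )
}

#' Flat parameter names for a network
#'
#' @param network A `crti_network`.
#' @return Character vector like `"k_f[1]" ... "k_cat[n]"`.
#' @export
parameter_names <- function(network) {
  n <- network$n_steps
  c(sprintf("k_f[%d]", seq_len(n + 1L)),
    sprintf("k_r[%d]", seq_len(n + 1L)),
    sprintf("k_cat[%d]", seq_len(n)))
}

params_to_vector <- function(params) {
  setNames(c(params$k_f, params$k_r, params$k_cat),
           parameter_names(list(n_steps = length(params$k_cat))))
}

vector_to_params <- function(x, n_steps) {
  kinetic_parameters(k_f = x[seq_len(n_steps + 1L)],
                     k_r = x[n_steps + 1L + seq_len(n_steps + 1L)],
                     k_cat = x[2L * (n_steps + 1L) + seq_len(n_steps)])
}

#' Draw random parameters uniformly within bounds
#'
#' Uniform (linear-scale) draws between the lower and upper bound of every
#' rate constant; used by the conservation test-bench and the
#' parameter-recovery harness. Uses the caller's RNG stream.
#'
#' @param network A `crti_network`.
#' @param bounds Bounds data.frame as from [default_parameter_bounds()].
#' @return A `kinetic_params` object.
#' @export
draw_parameters <- function(network, bounds = default_parameter_bounds(network)) {
  check_bounds(bounds, network)
  x <- runif(nrow(bounds), bounds$lower, bounds$upper)
  vector_to_params(x, network$n_steps)
}

check_bounds <- function(bounds, network, allow_equal = FALSE) {
  if (!is.data.frame(bounds) ||
      !all(c("parameter", "lower", "upper") %in% names(bounds))) {
    abort("bounds must have columns parameter, lower, upper",
          "carokin_invalid_input")
  }
  expected <- parameter_names(network)
  if (!identical(bounds$parameter, expected)) {
    abort("bounds must cover every free parameter, in canonical order",
          "carokin_invalid_input")
  }
  bad <- if (allow_equal) bounds$lower > bounds$upper else bounds$lower >= bounds$upper
  if (any(bad)) {
    abort("every lower bound must be < its upper bound",
          "carokin_invalid_input")
  }
  invisible(bounds)
}

#' Derive equilibrium and Michaelis constants from rate constants
#'
#' For every binding equilibrium, the dissociation constant
#' `K_d = k_r / k_f` (µM); for catalytic steps additionally the Michaelis
#' constant `K_m = (k_r + k_cat) / k_f` (µM). The terminal (dead-end)
#' complex has a `K_d` but no `K_m` or `k_cat`.
#'
#' @param params A `kinetic_params` object.
#' @return A data.frame with one row per complex: `step`, `K_d`, `K_m`,
#'   `k_cat` (the last two `NA` for the terminal complex).
#' @examples
#' # binding-bound extremes: K_d spans 1 to 100 µM
#' derive_constants(kinetic_parameters(c(0.1, 1), c(10, 1), 0.01))
#' @export
derive_constants <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(params$k_f == 0)) {
    abort("K_d is undefined when k_f == 0", "carokin_domain_error")
  }
  n <- length(params$k_cat)
  kcat_full <- c(params$k_cat, NA_real_)
  data.frame(
    step = seq_len(n + 1L),
    K_d = params$k_r / params$k_f,
    K_m = (params$k_r + kcat_full) / params$k_f,
    k_cat = kcat_full
  )
}
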