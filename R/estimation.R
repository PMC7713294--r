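#' Configuration of a particle-swarm fit
#'
#' Bounded particle-swarm estimation settings. Defaults follow the
#' COPASI-style protocol: 2000 iterations, bounds `k_f` in \[0.1, 1\]
#' µM^-1 s^-1, `k_r` in \[1, 10\] s^-1, `k_cat` in \[1e-5, 0.1\] s^-1, and
#' mean-square weighting of residuals per experiment and species. Swarm
#' hyperparameters use the standard constriction coefficients (inertia
#' 0.729, cognitive = social = 1.494). `k_cat` is searched in log10 space
#' (its bounds span four decades); `k_f` and `k_r` in linear space.
#' Objective evaluations during the search integrate at a relaxed tolerance
#' (`sim_rtol`) for speed; results are insensitive to this at the fitted
#' accuracy.
#'
#' @param network The `crti_network` being fitted.
#' @param iterations Swarm iterations (>= 1), default 2000.
#' @param swarm_size Number of particles (>= 2), default 50.
#' @param seed Integer seed; every stochastic element of the fit is
#'   determined by it.
#' @param weighting Residual weighting scheme: `"mean_square"` (default,
#'   `w = 1/mean(obs^2)`), `"squared_mean"` (`1/mean(obs)^2`),
#'   `"variance"` (`1/var(obs)`), or `"none"`.
#' @param bounds Bounds data.frame (`parameter`, `lower`, `upper`);
#'   defaults to [default_parameter_bounds()].
#' @param inertia,cognitive,social PSO constriction coefficients.
#' @param log_kcat Search `k_cat` in log10 space (default TRUE).
#' @param sim_rtol,sim_atol Integration tolerances used inside the
#'   objective for the bulk of the search.
#' @param refine_fraction Fraction of the final iterations run at the
#'   tighter `refine_rtol`/`refine_atol` tolerances (the loose-tolerance
#'   objective has an integration-noise floor that can hide the shallow
#'   valley around the optimum). Personal and global bests are
#'   re-evaluated at the switch.
#' @param refine_rtol,refine_atol Refinement-phase tolerances.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(network = build_network(4), iterations = 2000,
                       swarm_size = 50, seed = 1,
                       weighting = c("mean_square", "squared_mean",
                                     "variance", "none"),
                       bounds = default_parameter_bounds(network),
                       inertia = 0.729, cognitive = 1.494, social = 1.494,
                       log_kcat = TRUE, sim_rtol = 1e-4, sim_atol = 1e-7,
                       refine_fraction = 0.25, refine_rtol = 1e-5,
                       refine_atol = 1e-8) {
  weighting <- match.arg(weighting)
  if (!is_count(iterations)) {
    abort("`iterations` must be an integer >= 1", "carokin_invalid_input")
  }
  if (!is_count(swarm_size, min = 2L)) {
    abort("`swarm_size` must be an integer >= 2", "carokin_invalid_input")
  }
  check_bounds(bounds, network)
  if (!is_number(refine_fraction) || refine_fraction < 0 ||
      refine_fraction > 1) {
    abort("`refine_fraction` must be in [0, 1]", "carokin_invalid_input")
  }
  structure(list(iterations = as.integer(iterations),
                 swarm_size = as.integer(swarm_size), seed = as.integer(seed),
                 weighting = weighting, bounds = bounds, inertia = inertia,
                 cognitive = cognitive, social = social, log_kcat = log_kcat,
                 sim_rtol = sim_rtol, sim_atol = sim_atol,
                 refine_fraction = refine_fraction,
                 refine_rtol = refine_rtol, refine_atol = refine_atol),
            class = "fit_config")
}

check_experiments <- function(experiments, network) {
  if (!is.list(experiments) || length(experiments) == 0L) {
    abort("`experiments` must be a non-empty list of (assay, timecourse) pairs",
          "carokin_invalid_input")
  }
  for (i in seq_along(experiments)) {
    e <- experiments[[i]]
    if (!inherits(e$assay, "assay_spec") ||
        !inherits(e$timecourse, "crti_timecourse")) {
      abort(sprintf("experiment %d must have $assay (assay_spec) and $timecourse",
                    i), "carokin_invalid_input")
    }
    if (!isTRUE(all.equal(e$timecourse$time_min, e$assay$sampling_times))) {
      abort(sprintf("experiment %d: time course does not match assay sampling times",
                    i), "carokin_invalid_input")
    }
    if (length(intersect(timecourse_species(e$timecourse), network$chain)) == 0L) {
      abort(sprintf("experiment %d observes no network species", i),
            "carokin_invalid_input")
    }
  }
  invisible(TRUE)
}

experiment_weights <- function(obs, weighting) {
  # obs: numeric matrix (times x species) for one experiment
  vapply(seq_len(ncol(obs)), function(j) {
    x <- obs[, j]
    switch(weighting,
      mean_square = { m <- mean(x^2); if (m > 0) 1 / m else NA_real_ },
      squared_mean = { m <- mean(x); if (m > 0) 1 / m^2 else NA_real_ },
      variance = { v <- var(x); if (is.finite(v) && v > 0) 1 / v else NA_real_ },
      none = 1
    )
  }, numeric(1))
}

#' Weighted least-squares objective
#'
#' Simulates every experiment under `params` and returns
#' `sum_e sum_s w_es sum_t (sim - obs)^2` with, under the default
#' mean-square scheme, `w_es = 1 / mean(obs_es^2)` taken over that
#' experiment's observations of species `s`. Species whose observations are
#' all zero (or whose weight is undefined) are skipped. The weighting makes
#' each species' contribution invariant to rescaling its concentrations.
#'
#' @param params A `kinetic_params` object.
#' @param experiments List of experiments, each a list with elements
#'   `assay` ([assay_spec()]) and `timecourse` (observed `crti_timecourse`).
#' @param network The `crti_network` (default 4-step chain).
#' @param weighting Weighting scheme, see [fit_config()].
#' @param rtol,atol Integration tolerances.
#' @return Non-negative scalar.
#' @export
fit_objective <- function(params, experiments, network = build_network(4),
                          weighting = "mean_square",
                          rtol = 1e-8, atol = 1e-10) {
  check_experiments(experiments, network)
  total <- 0
  for (i in seq_along(experiments)) {
    e <- experiments[[i]]
    sp <- intersect(timecourse_species(e$timecourse),
                    c(network$chain, unique(network$branches$product)))
    obs <- as.matrix(e$timecourse[, sp, drop = FALSE])
    w <- experiment_weights(obs, weighting)
    sim <- tryCatch(
      simulate_timecourse(network, params, e$assay, rtol = rtol, atol = atol),
      error = function(err) {
        abort(sprintf("experiment %d: %s", i, conditionMessage(err)),
              "carokin_simulation_error")
      })
    simm <- as.matrix(sim[, sp, drop = FALSE])
    keep <- which(is.finite(w))
    for (j in keep) total <- total + w[j] * sum((simm[, j] - obs[, j])^2)
  }
  total
}

# Map particle coordinates <-> kinetic parameters (k_cat optionally log10)
encode_theta <- function(params, network, log_kcat) {
  x <- c(params$k_f, params$k_r,
         if (log_kcat) log10(params$k_cat) else params$k_cat)
  unname(x)
}

decode_theta <- function(x, network, log_kcat) {
  n <- network$n_steps
  kcat <- x[2L * (n + 1L) + seq_len(n)]
  if (log_kcat) kcat <- 10^kcat
  kinetic_parameters(k_f = x[seq_len(n + 1L)],
                     k_r = x[n + 1L + seq_len(n + 1L)], k_cat = kcat)
}

# Fast objective over a matrix of particle coordinates: all integration
# and residual accumulation happens in C++; identical in value to
# fit_objective() at the configured tolerances (asserted in the tests).
make_batch_objective <- function(network, experiments, config) {
  observables <- c(network$chain, unique(network$branches$product))
  prepared <- lapply(experiments, function(e) {
    sp <- intersect(timecourse_species(e$timecourse), observables)
    obs <- as.matrix(e$timecourse[, sp, drop = FALSE])
    list(
      y0 = as.numeric(initial_state(network, e$assay)),
      times_s = min_to_s(e$assay$sampling_times),
      obs = obs,
      obs_idx = as.integer(match(sp, observables) - 1L),
      weights = experiment_weights(obs, config$weighting),
      args = network_cpp_args(network, e$assay$phytoene_influx)
    )
  })
  n <- network$n_steps
  kcat_cols <- 2L * (n + 1L) + seq_len(n)
  function(X, rtol = config$sim_rtol, atol = config$sim_atol) {
    P <- X
    if (config$log_kcat) P[, kcat_cols] <- 10^P[, kcat_cols]
    total <- numeric(nrow(X))
    for (pe in prepared) {
      a <- pe$args
      total <- total + objective_batch_cpp(
        P, a$n_steps, a$bsrc, a$bdst, a$bvmax, a$bkm, a$influx,
        a$n_branch_species, pe$y0, pe$times_s, pe$obs, pe$obs_idx,
        pe$weights, rtol, atol, 5e5)
    }
    total
  }
}

search_bounds <- function(config, network) {
  n <- network$n_steps
  lb <- config$bounds$lower
  ub <- config$bounds$upper
  if (config$log_kcat) {
    idx <- 2L * (n + 1L) + seq_len(n)
    lb[idx] <- log10(lb[idx])
    ub[idx] <- log10(ub[idx])
  }
  list(lb = lb, ub = ub)
}

#' Fit rate constants by bounded particle-swarm optimisation
#'
#' Minimises [fit_objective()] over the rate constants within bounds using
#' a constriction-coefficient particle swarm with reflecting boundary
#' handling, augmented with a guaranteed-convergence local-search step
#' around the global best (one extra trial point per iteration in a box
#' that expands on success and shrinks on failure), which keeps descent
#' going along the flat parameter ridges typical of this model. Fully
#' deterministic given `config$seed`. Particles whose objective evaluates
#' non-finite are assigned an infinite objective (and counted). The
#' returned trace is monotone non-increasing within each integration
#' fidelity phase; at the refinement switch the remembered bests are
#' re-scored at the tighter tolerance, which can raise the recorded
#' objective honestly.
#'
#' @param network A `crti_network`.
#' @param experiments Experiments as in [fit_objective()].
#' @param config A [fit_config()].
#' @return An object of class `fit_result` with elements `best_params`,
#'   `objective_value`, `trace` (best objective per iteration),
#'   `derived_constants` (per-step `K_d`, `K_m`, `k_cat`), `seed`,
#'   `config`, and `n_failed_evals`.
#' @export
fit_pso <- function(network, experiments, config = fit_config(network)) {
  stopifnot(inherits(network, "crti_network"), inherits(config, "fit_config"))
  check_experiments(experiments, network)
  check_bounds(config$bounds, network, allow_equal = TRUE)

  obj_batch <- make_batch_objective(network, experiments, config)

  sb <- search_bounds(config, network)
  d <- length(sb$lb)
  range <- sb$ub - sb$lb
  fixed <- range == 0

  n_refine <- as.integer(floor(config$iterations * config$refine_fraction))
  switch_iter <- config$iterations - n_refine + 1L

  res <- with_preserved_seed(config$seed, {
    X <- matrix(runif(config$swarm_size * d, rep(sb$lb, each = config$swarm_size),
                      rep(sb$ub, each = config$swarm_size)),
                nrow = config$swarm_size)
    V <- matrix(runif(config$swarm_size * d, -1, 1), nrow = config$swarm_size) *
      rep(range, each = config$swarm_size) * 0.25
    X[, fixed] <- rep(sb$lb[fixed], each = config$swarm_size)
    V[, fixed] <- 0

    rtol <- config$sim_rtol
    atol <- config$sim_atol
    fx <- obj_batch(X, rtol, atol)
    n_failed <- sum(!is.finite(fx))
    if (all(!is.finite(fx))) {
      abort("all particles failed simulation at initialization",
            "carokin_initialization_error")
    }
    P <- X
    fp <- fx
    g <- which.min(fp)
    gbest <- X[g, ]
    fgbest <- fp[g]
    trace <- numeric(config$iterations)
    rho <- 0.1  # GCPSO local-search radius, in units of the bound range
    free <- which(!fixed)

    for (iter in seq_len(config$iterations)) {
      if (n_refine > 0L && iter == switch_iter) {
        # refinement phase: tighter integration tolerances, and the swarm
        # restarts in a contracted box around the incumbent best (an
        # intensive local particle swarm along the remaining valley);
        # re-scoring drops spurious loose-tolerance minima
        rtol <- config$refine_rtol
        atol <- config$refine_atol
        fgbest <- obj_batch(matrix(gbest, nrow = 1), rtol, atol)[1]
        spread <- 0.05 * range
        X <- matrix(rep(gbest, each = config$swarm_size),
                    nrow = config$swarm_size) +
          matrix(runif(config$swarm_size * d, -1, 1),
                 nrow = config$swarm_size) *
          rep(spread, each = config$swarm_size)
        X <- pmin(pmax(X, rep(sb$lb, each = config$swarm_size)),
                  rep(sb$ub, each = config$swarm_size))
        X[1, ] <- gbest
        X[, fixed] <- rep(sb$lb[fixed], each = config$swarm_size)
        V <- matrix(runif(config$swarm_size * d, -1, 1),
                    nrow = config$swarm_size) *
          rep(spread, each = config$swarm_size) * 0.5
        V[, fixed] <- 0
        fx <- obj_batch(X, rtol, atol)
        n_failed <- n_failed + sum(!is.finite(fx))
        P <- X
        fp <- fx
        g <- which.min(fp)
        if (fp[g] < fgbest) { fgbest <- fp[g]; gbest <- P[g, ] }
        rho <- 0.02
      }
      r1 <- matrix(runif(config$swarm_size * d), nrow = config$swarm_size)
      r2 <- matrix(runif(config$swarm_size * d), nrow = config$swarm_size)
      V <- config$inertia * V +
        config$cognitive * r1 * (P - X) +
        config$social * r2 * sweep(X, 2, gbest, function(x, g) g - x)
      # velocity clamp at one bound-range per iteration
      V <- pmin(pmax(V, rep(-range, each = config$swarm_size)),
                rep(range, each = config$swarm_size))
      X <- X + V
      # reflecting bounds
      for (j in seq_len(d)) {
        if (fixed[j]) { X[, j] <- sb$lb[j]; V[, j] <- 0; next }
        lo <- X[, j] < sb$lb[j]
        X[lo, j] <- 2 * sb$lb[j] - X[lo, j]
        hi <- X[, j] > sb$ub[j]
        X[hi, j] <- 2 * sb$ub[j] - X[hi, j]
        V[lo | hi, j] <- -V[lo | hi, j]
        X[, j] <- pmin(pmax(X[, j], sb$lb[j]), sb$ub[j])
      }
      fx <- obj_batch(X, rtol, atol)
      n_failed <- n_failed + sum(!is.finite(fx))
      better <- fx < fp
      P[better, ] <- X[better, , drop = FALSE]
      fp[better] <- fx[better]
      g <- which.min(fp)
      if (fp[g] < fgbest) { fgbest <- fp[g]; gbest <- P[g, ] }

      # guaranteed-convergence step: a trial point in a shrinking box
      # around the global best keeps descent going once the swarm
      # stagnates on a flat ridge (van den Bergh's GCPSO idea)
      if (length(free)) {
        trial <- gbest
        trial[free] <- trial[free] +
          rho * range[free] * runif(length(free), -1, 1)
        trial <- pmin(pmax(trial, sb$lb), sb$ub)
        ftrial <- obj_batch(matrix(trial, nrow = 1), rtol, atol)
        if (is.finite(ftrial) && ftrial < fgbest) {
          fgbest <- ftrial
          gbest <- trial
          rho <- min(rho * 2, 0.5)
        } else {
          rho <- max(rho * 0.7, 1e-8)
        }
      }
      trace[iter] <- fgbest
    }
    list(gbest = gbest, fgbest = fgbest, trace = trace, n_failed = n_failed)
  })

  if (res$n_failed > 0) {
    warn(sprintf("%d particle evaluations failed and were discarded",
                 res$n_failed), "carokin_failed_particles")
  }
  best <- decode_theta(res$gbest, network, config$log_kcat)
  structure(list(best_params = best, objective_value = res$fgbest,
                 trace = res$trace, derived_constants = derive_constants(best),
                 seed = config$seed, config = config,
                 n_failed_evals = res$n_failed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Particle-swarm fit (seed %d, %d iterations, swarm %d)\n",
              x$seed, x$config$iterations, x$config$swarm_size))
  cat(sprintf("  objective : %.6g\n", x$objective_value))
  cat("  derived constants (per complex):\n")
  print(x$derived_constants, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Objective profile of a single parameter
#'
#' Identifiability diagnostic: fixes one rate constant at each grid value
#' and re-fits all others, returning the profile of best objective values.
#' A flat profile over a wide grid means the data do not constrain the
#' parameter -- typically the case for the binding constants behind `K_d`,
#' which is why fitted `K_d` values deserve caution, while the catalytic
#' constants profile sharply on rich data.
#'
#' @param network A `crti_network`.
#' @param experiments Experiments as in [fit_objective()].
#' @param config A [fit_config()]; its seed derives the per-grid-point
#'   refit seeds.
#' @param parameter Parameter name, e.g. `"k_cat[1]"` (see
#'   [parameter_names()]).
#' @param grid Numeric values (within the parameter's bounds) at which to
#'   fix it.
#' @param vary_seed Use a different refit seed per grid point (default).
#'   With `FALSE` every refit shares `config$seed`, so a parameter the
#'   objective ignores produces an exactly flat profile.
#' @return A data.frame with columns `value` and `objective`, of class
#'   `identifiability_profile`.
#' @export
profile_identifiability <- function(network, experiments, config, parameter,
                                    grid, vary_seed = TRUE) {
  stopifnot(inherits(config, "fit_config"))
  idx <- match(parameter, parameter_names(network))
  if (is.na(idx)) {
    abort(sprintf("'%s' does not name a free parameter", parameter),
          "carokin_invalid_input")
  }
  b <- config$bounds
  if (any(grid < b$lower[idx] | grid > b$upper[idx])) {
    abort("profile grid must lie within the parameter's bounds",
          "carokin_invalid_input")
  }
  objective <- vapply(seq_along(grid), function(k) {
    cfg <- config
    cfg$bounds$lower[idx] <- grid[k]
    cfg$bounds$upper[idx] <- grid[k]
    cfg$seed <- if (vary_seed) config$seed + k - 1L else config$seed
    fit_pso(network, experiments, cfg)$objective_value
  }, numeric(1))
  structure(data.frame(value = grid, objective = objective),
            class = c("identifiability_profile", "data.frame"),
            parameter = parameter)
}
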