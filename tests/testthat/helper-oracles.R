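# Independent oracles and small fixtures. The reference RHS below is a
# deliberate re-derivation (per-reaction stoichiometry loop), kept separate
# from the package's C++ implementation so the two can disagree.

reference_rhs <- function(state, params, network, influx = 0) {
  n <- network$n_steps
  sn <- network$state_names
  dy <- setNames(numeric(length(sn)), sn)
  E <- state[["E"]]
  for (i in seq_len(n + 1L)) {
    s <- network$chain[i]
    cplx <- network$complexes[i]
    v_bind <- params$k_f[i] * E * state[[s]]
    v_unbind <- params$k_r[i] * state[[cplx]]
    # E + S_i -> ES_i
    dy[s] <- dy[s] - v_bind
    dy["E"] <- dy["E"] - v_bind
    dy[cplx] <- dy[cplx] + v_bind
    # ES_i -> E + S_i
    dy[s] <- dy[s] + v_unbind
    dy["E"] <- dy["E"] + v_unbind
    dy[cplx] <- dy[cplx] - v_unbind
    if (i <= n) {
      # ES_i -> E + S_{i+1}
      v_cat <- params$k_cat[i] * state[[cplx]]
      dy[cplx] <- dy[cplx] - v_cat
      dy["E"] <- dy["E"] + v_cat
      dy[network$chain[i + 1L]] <- dy[network$chain[i + 1L]] + v_cat
    }
  }
  if (nrow(network$branches)) {
    for (b in seq_len(nrow(network$branches))) {
      br <- network$branches[b, ]
      v <- br$vmax * state[[br$source]] / (br$km + state[[br$source]])
      dy[br$source] <- dy[br$source] - v
      dy[br$product] <- dy[br$product] + v
    }
  }
  dy["phytoene"] <- dy["phytoene"] + influx
  dy
}

# closed-form equilibrium of E + S <=> ES (quadratic in ES)
binding_equilibrium <- function(E_total, S_total, K_d) {
  b <- E_total + S_total + K_d
  (b - sqrt(b^2 - 4 * E_total * S_total)) / 2
}

random_state <- function(network, scale = 5) {
  setNames(runif(length(network$state_names), 0, scale),
           network$state_names)
}

fast_params <- function() {
  kinetic_parameters(rep(0.5, 5), rep(5, 5), c(0.02, 0.03, 0.03, 0.012))
}

# a tiny but non-trivial PSO configuration for unit tests
tiny_fit_config <- function(network, seed = 1, ...) {
  fit_config(network, iterations = 40, swarm_size = 12, seed = seed, ...)
}

make_experiment <- function(network, params, assay,
                            noise = noise_spec(cv = 0, floor = 0, seed = 1)) {
  sc <- structure(list(label = "fixture", network = network,
                       true_params = params, assay = assay, noise = noise),
                  class = "scenario_preset")
  list(assay = assay, timecourse = generate_timecourse(sc))
}
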