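#' Build a desaturation reaction network
#'
#' Constructs the mass-action network for `n_steps` successive desaturations
#' of phytoene with explicit enzyme binding: every chain species `S_i`
#' (including the terminal product) has its own binding equilibrium
#' `E + S_i <=> ES_i`, and every non-terminal complex a catalytic step
#' `ES_i -> E + S_(i+1)`. The terminal complex is a dead end, which is the
#' model's product-inhibition term. The default 4-step chain
#' (phytoene to lycopene) is the fitted model; the steps to
#' didehydrolycopene and tetradehydrolycopene are only reachable in
#' `extended` mode, which also admits irreversible Michaelis-Menten
#' cyclisation branches along the canonical cyclase topology
#' (see [cyclisation_edges()]).
#'
#' @param n_steps Number of catalytic desaturation steps (1-6; > 4 requires
#'   `extended = TRUE`). Default 4.
#' @param extended Enable chain steps 5-6 and cyclisation branches.
#' @param branch_spec Optional cyclisation branches: a data.frame (or list
#'   of lists) with columns `source`, `product` and per-branch rate-law
#'   parameters `vmax` (µM/s) and `km` (µM). `product` may be omitted when
#'   the canonical edge is meant. Branch sources must already be present in
#'   the network (chain species or an earlier branch product).
#' @return An object of class `crti_network`.
#' @examples
#' net <- build_network(4)
#' net
#' ext <- build_network(5, extended = TRUE,
#'                      branch_spec = data.frame(source = "lycopene",
#'                                               vmax = 2e-4, km = 5))
#' @export
build_network <- function(n_steps = 4, extended = FALSE, branch_spec = NULL) {
  if (!is_count(n_steps)) {
    abort("`n_steps` must be a single integer >= 1", "carokin_invalid_network")
  }
  n_steps <- as.integer(n_steps)
  if (n_steps > 6L) {
    abort("the desaturation chain has at most 6 steps (to tetradehydrolycopene)",
          "carokin_invalid_network")
  }
  if (!is_flag(extended)) {
    abort("`extended` must be TRUE or FALSE", "carokin_invalid_input")
  }
  if (n_steps > 4L && !extended) {
    abort("chain steps 5-6 require `extended = TRUE`",
          "carokin_invalid_network")
  }
  if (!is.null(branch_spec) && !extended) {
    abort("cyclisation branches require `extended = TRUE`",
          "carokin_invalid_network")
  }

  chain <- chain_species_names()[seq_len(n_steps + 1L)]
  branches <- normalise_branch_spec(branch_spec, chain)
  branch_products <- unique(branches$product)

  species <- rbind(
    cbind(species_info(chain), role = "chain"),
    if (length(branch_products)) {
      cbind(species_info(branch_products), role = "branch")
    }
  )
  rownames(species) <- NULL

  complexes <- paste0("ES_", chain)
  state_names <- c(chain, "E", complexes, branch_products)

  structure(
    list(
      n_steps = n_steps,
      enzyme = "CrtI",
      species = species,
      chain = chain,
      complexes = complexes,
      branches = branches,
      extended = extended,
      state_names = state_names,
      n_parameters = 3L * n_steps + 2L
    ),
    class = "crti_network"
  )
}

normalise_branch_spec <- function(branch_spec, chain) {
  empty <- data.frame(source = character(), product = character(),
                      vmax = numeric(), km = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(branch_spec)) return(empty)
  if (is.list(branch_spec) && !is.data.frame(branch_spec)) {
    branch_spec <- do.call(rbind, lapply(branch_spec, function(b) {
      as.data.frame(b[intersect(names(b), c("source", "product", "vmax", "km"))],
                    stringsAsFactors = FALSE)
    }))
  }
  if (!is.data.frame(branch_spec) || is.null(branch_spec$source)) {
    abort("`branch_spec` must provide a `source` column",
          "carokin_invalid_input")
  }
  edges <- cyclisation_edges()
  src <- as.character(branch_spec$source)
  prod <- if (is.null(branch_spec$product)) {
    edges$product[match(src, edges$source)]
  } else {
    p <- as.character(branch_spec$product)
    ifelse(is.na(p) | p == "", edges$product[match(src, edges$source)], p)
  }
  known <- paste(edges$source, edges$product)
  bad <- !(paste(src, prod) %in% known)
  if (any(bad)) {
    abort(sprintf("not a canonical cyclisation edge: %s",
                  paste(src[bad], "->", prod[bad], collapse = ", ")),
          "carokin_invalid_network")
  }
  vmax <- if (is.null(branch_spec$vmax)) rep(0, length(src)) else as.numeric(branch_spec$vmax)
  km <- if (is.null(branch_spec$km)) rep(1, length(src)) else as.numeric(branch_spec$km)
  if (any(!is.finite(vmax)) || any(vmax < 0) || any(!is.finite(km)) || any(km <= 0)) {
    abort("branch `vmax` must be >= 0 and `km` > 0", "carokin_domain_error")
  }

  # sources must exist in the chain or among products of earlier branches
  avail <- chain
  for (i in seq_along(src)) {
    if (!(src[i] %in% avail)) {
      abort(sprintf("branch source '%s' is not in the network", src[i]),
            "carokin_unknown_species")
    }
    avail <- union(avail, prod[i])
  }
  data.frame(source = src, product = prod, vmax = vmax, km = km,
             stringsAsFactors = FALSE)
}

#' @export
print.crti_network <- function(x, ...) {
  cat(sprintf("CrtI desaturation network: %d catalytic steps%s\n",
              x$n_steps, if (x$extended) " (extended)" else ""))
  cat(sprintf("  chain species : %s\n", paste(x$chain, collapse = " -> ")))
  cat(sprintf("  complexes     : %d (terminal complex %s is a dead end)\n",
              length(x$complexes), x$complexes[length(x$complexes)]))
  cat(sprintf("  free params   : %d (%d k_f, %d k_r, %d k_cat)\n",
              x$n_parameters, x$n_steps + 1L, x$n_steps + 1L, x$n_steps))
  if (nrow(x$branches)) {
    cat("  cyclisation   :",
        paste(x$branches$source, "->", x$branches$product, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Plain-text reaction summary of a network
#'
#' Lists every reaction with its mass-action (or Michaelis-Menten, for
#' cyclisation branches) rate expression.
#'
#' @param network A `crti_network`.
#' @param params Optional [kinetic_parameters()] to substitute numeric
#'   values into the rate expressions.
#' @return A character vector, one reaction per element.
#' @export
network_summary <- function(network, params = NULL) {
  stopifnot(inherits(network, "crti_network"))
  n <- network$n_steps
  fmt <- function(sym, i, vec) {
    if (is.null(params)) sprintf("%s[%d]", sym, i) else format(vec[i], digits = 6)
  }
  lines <- character(0)
  for (i in seq_len(n + 1L)) {
    s <- network$chain[i]
    cplx <- network$complexes[i]
    lines <- c(lines, sprintf(
      "E + %s <=> %s   v = %s*E*%s - %s*%s", s, cplx,
      fmt("k_f", i, params$k_f), s, fmt("k_r", i, params$k_r), cplx))
    if (i <= n) {
      lines <- c(lines, sprintf(
        "%s -> E + %s   v = %s*%s", cplx, network$chain[i + 1L],
        fmt("k_cat", i, params$k_cat), cplx))
    }
  }
  if (nrow(network$branches)) {
    for (b in seq_len(nrow(network$branches))) {
      br <- network$branches[b, ]
      lines <- c(lines, sprintf(
        "%s -> %s   v = %g*%s/(%g + %s)  [cyclisation]",
        br$source, br$product, br$vmax, br$source, br$km, br$source))
    }
  }
  lines
}

# 0-based C++ call arguments describing a network + branch rates
network_cpp_args <- function(network, influx = 0) {
  b <- network$branches
  list(
    n_steps = network$n_steps,
    bsrc = as.integer(match(b$source, network$state_names) - 1L),
    bdst = as.integer(match(b$product, network$state_names) - 1L),
    bvmax = as.numeric(b$vmax),
    bkm = as.numeric(b$km),
    influx = influx,
    n_branch_species = length(unique(b$product))
  )
}
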