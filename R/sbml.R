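#' Export a network to SBML Level 3
#'
#' Writes the reaction network (species, parameters, mass-action binding
#' and catalysis, Michaelis-Menten cyclisation branches, optional phytoene
#' influx) as an SBML Level 3 Version 1 core document, for cross-checking
#' in independent simulators. Units follow the package convention: µM and
#' seconds.
#'
#' @param network A `crti_network`.
#' @param params A matching `kinetic_params` object.
#' @param path Output file.
#' @param assay Optional [assay_spec()] supplying initial concentrations
#'   and influx; defaults to 10 µM phytoene, 0.83 µM enzyme.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, params, path, assay = assay_spec()) {
  stopifnot(inherits(network, "crti_network"))
  check_state_params(initial_state(network, assay), params, network)
  n <- network$n_steps
  y0 <- initial_state(network, assay)

  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "crti_desaturation")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")

  lof <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in network$state_names) {
    xml2::xml_add_child(lof, "species", id = s, compartment = "cell",
                        initialConcentration = format(y0[[s]], digits = 10),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  lop <- xml2::xml_add_child(model, "listOfParameters")
  add_par <- function(id, value) {
    xml2::xml_add_child(lop, "parameter", id = id,
                        value = format(value, digits = 10), constant = "true")
  }
  for (i in seq_len(n + 1L)) {
    add_par(sprintf("k_f_%d", i), params$k_f[i])
    add_par(sprintf("k_r_%d", i), params$k_r[i])
  }
  for (i in seq_len(n)) add_par(sprintf("k_cat_%d", i), params$k_cat[i])

  lor <- xml2::xml_add_child(model, "listOfReactions")
  mathml <- "http://www.w3.org/1998/Math/MathML"
  ci_s <- function(x) sprintf("<ci>%s</ci>", x)
  apply_s <- function(op, ...) {
    sprintf("<apply><%s/>%s</apply>", op, paste(..., collapse = ""))
  }
  math_of <- function(s) xml2::read_xml(sprintf("<math xmlns='%s'>%s</math>", mathml, s))

  add_reaction2 <- function(id, reactants, products, math_str) {
    rx <- xml2::xml_add_child(lor, "reaction", id = id, reversible = "false",
                              fast = "false")
    if (length(reactants)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (r in reactants) {
        xml2::xml_add_child(lr, "speciesReference", species = r,
                            stoichiometry = "1", constant = "true")
      }
    }
    if (length(products)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (p in products) {
        xml2::xml_add_child(lp, "speciesReference", species = p,
                            stoichiometry = "1", constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    xml2::xml_add_child(kl, math_of(math_str))
    invisible(rx)
  }

  for (i in seq_len(n + 1L)) {
    s <- network$chain[i]
    cplx <- network$complexes[i]
    add_reaction2(sprintf("binding_%d", i), c("E", s), cplx,
                  apply_s("times", ci_s(sprintf("k_f_%d", i)), ci_s("E"), ci_s(s)))
    add_reaction2(sprintf("unbinding_%d", i), cplx, c("E", s),
                  apply_s("times", ci_s(sprintf("k_r_%d", i)), ci_s(cplx)))
    if (i <= n) {
      add_reaction2(sprintf("catalysis_%d", i), cplx,
                    c("E", network$chain[i + 1L]),
                    apply_s("times", ci_s(sprintf("k_cat_%d", i)), ci_s(cplx)))
    }
  }
  if (nrow(network$branches)) {
    for (b in seq_len(nrow(network$branches))) {
      br <- network$branches[b, ]
      num <- apply_s("times", sprintf("<cn>%s</cn>", format(br$vmax, digits = 10)),
                     ci_s(br$source))
      den <- apply_s("plus", sprintf("<cn>%s</cn>", format(br$km, digits = 10)),
                     ci_s(br$source))
      add_reaction2(sprintf("cyclisation_%d", b), br$source, br$product,
                    apply_s("divide", num, den))
    }
  }
  if (assay$phytoene_influx > 0) {
    add_reaction2("phytoene_influx", character(0), "phytoene",
                  sprintf("<cn>%s</cn>", format(assay$phytoene_influx,
                                                digits = 10)))
  }

  write_atomic(function(p) xml2::write_xml(doc, p), path)
}
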