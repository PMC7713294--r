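#' Canonical carotene species table
#'
#' The carotenes handled by the package, each described by the number of
#' CrtI-added double bonds relative to phytoene (`desaturation_index`,
#' 0-6) and the number of beta-ionone rings (`cycle_count`, 0-2). The
#' acyclic desaturation chain runs phytoene -> phytofluene -> zeta-carotene
#' -> neurosporene -> lycopene -> didehydrolycopene ->
#' tetradehydrolycopene; cyclisation preserves the desaturation index and
#' increments the cycle count.
#'
#' @return A data.frame with columns `name`, `desaturation_index`,
#'   `cycle_count`.
#' @examples
#' carotene_species()
#' @export
carotene_species <- function() {
  data.frame(
    name = c(
      "phytoene", "phytofluene", "zeta_carotene", "neurosporene",
      "lycopene", "didehydrolycopene", "tetradehydrolycopene",
      "beta_zeacarotene", "dihydro_beta_carotene",
      "gamma_carotene", "beta_carotene",
      "torulene", "dehydro_beta_carotene"
    ),
    desaturation_index = c(0:6, 3L, 3L, 4L, 4L, 5L, 5L),
    cycle_count = c(rep(0L, 7), 1L, 2L, 1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

# chain species in desaturation order
chain_species_names <- function() carotene_species()$name[1:7]

#' Canonical cyclisation edges
#'
#' The lycopene-cyclase reactions of the carotene pathway: each edge adds
#' one ring while keeping the desaturation index, so neurosporene leads to
#' beta-zeacarotene and then dihydro-beta-carotene, lycopene to
#' gamma-carotene and beta-carotene, and didehydrolycopene to torulene and
#' dehydro-beta-carotene.
#'
#' @return A data.frame with columns `source` and `product`.
#' @export
cyclisation_edges <- function() {
  data.frame(
    source = c("neurosporene", "beta_zeacarotene", "lycopene",
               "gamma_carotene", "didehydrolycopene", "torulene"),
    product = c("beta_zeacarotene", "dihydro_beta_carotene", "gamma_carotene",
                "beta_carotene", "torulene", "dehydro_beta_carotene"),
    stringsAsFactors = FALSE
  )
}

species_info <- function(names) {
  tab <- carotene_species()
  idx <- match(names, tab$name)
  if (anyNA(idx)) {
    abort(sprintf("unknown carotene species: %s",
                  paste(names[is.na(idx)], collapse = ", ")),
          "carokin_unknown_species")
  }
  tab[idx, , drop = FALSE]
}
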