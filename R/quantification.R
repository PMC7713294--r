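#' Read a molar extinction coefficient table
#'
#' Columns: `species`, `epsilon_M_cm` (M^-1 cm^-1), `wavelength_nm`, and
#' optional `surrogate_of` recording borrowed coefficients. The shipped
#' table (`inst/extdata/extinction_coefficients.csv`) carries documented
#' literature *placeholder* values -- editable, and deliberately not
#' presented as ground truth; quantitative work should supply a curated
#' table.
#'
#' @param path CSV path; defaults to the shipped placeholder table.
#' @return A data.frame of class `extinction_table`.
#' @export
extinction_table <- function(path = system.file("extdata",
                                                "extinction_coefficients.csv",
                                                package = "carokin")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "epsilon_M_cm", "wavelength_nm")
  if (!all(need %in% names(df))) {
    abort(sprintf("extinction table must have columns %s",
                  paste(need, collapse = ", ")), "carokin_format_error")
  }
  if (is.null(df$surrogate_of)) df$surrogate_of <- ""
  df$surrogate_of[is.na(df$surrogate_of)] <- ""
  if (any(!is.na(df$epsilon_M_cm) & df$epsilon_M_cm <= 0)) {
    abort("extinction coefficients must be > 0", "carokin_domain_error")
  }
  class(df) <- c("extinction_table", "data.frame")
  df
}

# Closest-molecule substitutions used when no coefficient is reported.
builtin_surrogates <- function() {
  c(tetradehydrolycopene = "didehydrolycopene",
    dehydro_beta_carotene = "beta_zeacarotene")
}

#' Resolve the extinction coefficient for a species
#'
#' Returns the species' own table entry, except for the two species
#' quantified via their closest molecules: tetradehydrolycopene always uses
#' didehydrolycopene's coefficient and dehydro-beta-carotene always uses
#' beta-zeacarotene's, each flagged through `surrogate_of`. Table-declared
#' surrogates (rows with `surrogate_of` set and no own coefficient) are
#' honoured the same way. Surrogate resolution never chains: a surrogate's
#' own `surrogate_of` is ignored.
#'
#' @param species Species name.
#' @param table An [extinction_table()].
#' @return A list of class `extinction_entry` with `species`, `epsilon`,
#'   `wavelength`, `surrogate_of` (`NA` when the coefficient is the
#'   species' own).
#' @export
resolve_epsilon <- function(species, table = extinction_table()) {
  stopifnot(is.character(species), length(species) == 1L)
  own <- function(name) {
    i <- match(name, table$species)
    if (is.na(i) || is.na(table$epsilon_M_cm[i]) || table$epsilon_M_cm[i] <= 0) {
      return(NULL)
    }
    list(epsilon = table$epsilon_M_cm[i], wavelength = table$wavelength_nm[i])
  }
  surrogate <- unname(builtin_surrogates()[species])
  if (is.na(surrogate)) {
    i <- match(species, table$species)
    if (!is.na(i) && nzchar(table$surrogate_of[i]) && is.null(own(species))) {
      surrogate <- table$surrogate_of[i]
    } else {
      surrogate <- NA_character_
    }
  }
  source_name <- if (is.na(surrogate)) species else surrogate
  entry <- own(source_name)
  if (is.null(entry)) {
    abort(sprintf("no extinction coefficient for '%s'%s", species,
                  if (!is.na(surrogate)) sprintf(" (surrogate '%s' missing)",
                                                 surrogate) else ""),
          "carokin_missing_coefficient")
  }
  structure(list(species = species, epsilon = entry$epsilon,
                 wavelength = entry$wavelength, surrogate_of = surrogate),
            class = "extinction_entry")
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' `c = A / (epsilon * l)`, converted to µM.
#'
#' @param absorbance Absorbance (AU), >= 0.
#' @param entry An `extinction_entry` from [resolve_epsilon()], or a list
#'   with an `epsilon` element (M^-1 cm^-1).
#' @param path_length Optical path length in cm (> 0), default 1.
#' @return Concentration in µM.
#' @examples
#' e <- list(epsilon = 1e5)
#' concentration_from_absorbance(0.1, e) # 1 µM
#' @export
concentration_from_absorbance <- function(absorbance, entry, path_length = 1) {
  eps <- entry$epsilon
  if (!is_number(eps) || eps <= 0 || !is_number(path_length) || path_length <= 0) {
    abort("epsilon and path length must be > 0", "carokin_domain_error")
  }
  if (any(!is.finite(absorbance)) || any(absorbance < 0)) {
    abort("absorbance must be >= 0", "carokin_domain_error")
  }
  absorbance / (eps * path_length) * 1e6
}

#' Summarise a carotene composition
#'
#' Computes, after censoring species below the detection limit: the
#' fraction of total carotene per species; the fraction among desaturated
#' products (phytoene and any other 0-desaturation species excluded); and
#' the concentration grid indexed by (desaturation index 0-6, cycle count
#' 0-2). Fractions are computed after censoring, mirroring how HPLC
#' patterns are reported.
#'
#' @param concentrations Named numeric vector, µM, names from
#'   [carotene_species()].
#' @param detection_limit Censoring threshold, µM (default 0).
#' @return An object of class `carotene_pattern` with elements
#'   `fractions_total`, `fractions_desaturated`, `grid` (7 x 3 matrix),
#'   `total`, `detected`, `empty`.
#' @examples
#' pattern_summary(c(phytoene = 5, phytofluene = 3, lycopene = 2))
#' @export
pattern_summary <- function(concentrations, detection_limit = 0) {
  if (is.null(names(concentrations)) || !is.numeric(concentrations)) {
    abort("`concentrations` must be a named numeric vector",
          "carokin_invalid_input")
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    abort("concentrations must be finite and >= 0", "carokin_domain_error")
  }
  info <- species_info(names(concentrations))
  grid <- matrix(0, nrow = 7, ncol = 3,
                 dimnames = list(desaturations = 0:6, cycles = 0:2))
  detected <- concentrations[concentrations >= detection_limit &
                               concentrations > 0]
  if (length(detected) == 0L) {
    return(structure(list(fractions_total = numeric(0),
                          fractions_desaturated = numeric(0), grid = grid,
                          total = 0, detected = character(0), empty = TRUE),
                     class = "carotene_pattern"))
  }
  dinfo <- species_info(names(detected))
  total <- sum(detected)
  fractions_total <- detected / total
  desat <- detected[dinfo$desaturation_index >= 1L]
  fractions_desaturated <- if (length(desat)) desat / sum(desat) else numeric(0)
  for (i in seq_along(detected)) {
    r <- dinfo$desaturation_index[i] + 1L
    c <- dinfo$cycle_count[i] + 1L
    grid[r, c] <- grid[r, c] + detected[[i]]
  }
  structure(list(fractions_total = fractions_total,
                 fractions_desaturated = fractions_desaturated, grid = grid,
                 total = total, detected = names(detected), empty = FALSE),
            class = "carotene_pattern")
}

#' @export
print.carotene_pattern <- function(x, ...) {
  if (x$empty) {
    cat("Carotene pattern: nothing above the detection limit\n")
    return(invisible(x))
  }
  cat(sprintf("Carotene pattern (total %.4g µM)\n", x$total))
  cat("  fraction of total carotene:\n")
  for (s in names(x$fractions_total)) {
    cat(sprintf("    %-22s %6.1f%%\n", s, 100 * x$fractions_total[[s]]))
  }
  if (length(x$fractions_desaturated)) {
    cat("  fraction of desaturated products:\n")
    for (s in names(x$fractions_desaturated)) {
      cat(sprintf("    %-22s %6.1f%%\n", s, 100 * x$fractions_desaturated[[s]]))
    }
  }
  invisible(x)
}

#' Write a pattern summary to CSV (fractions) and a grid matrix file
#'
#' @param pattern A `carotene_pattern`.
#' @param path Output CSV for per-species fractions; the
#'   desaturation-by-cycle grid goes to `<path>` with suffix `_grid.csv`.
#' @return Paths, invisibly.
#' @export
write_pattern_summary <- function(pattern, path) {
  stopifnot(inherits(pattern, "carotene_pattern"))
  sp <- pattern$detected
  df <- data.frame(
    species = sp,
    fraction_total = as.numeric(pattern$fractions_total[sp]),
    fraction_desaturated = as.numeric(pattern$fractions_desaturated[sp])
  )
  write_atomic(function(p) write.csv(df, p, row.names = FALSE), path)
  grid_path <- sub("(\\.csv)?$", "_grid.csv", path)
  write_atomic(function(p) write.csv(as.data.frame(pattern$grid), p), grid_path)
  invisible(c(path, grid_path))
}
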