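#' Describe an in vitro desaturation assay
#'
#' The experimental design of a purified-enzyme assay: initial phytoene
#' (delivered in liposomes), total enzyme, the sampling schedule, and the
#' HPLC detection limit. The standard assay contains 5 nmol phytoene in a
#' 0.5 mL reaction (10 µM) and 25 µg enzyme.
#'
#' @param initial_phytoene Initial phytoene, µM (> 0; may be 0 when a
#'   `phytoene_influx` feeds the system, as in the in vivo surrogate).
#' @param enzyme_total Total enzyme, µM (>= 0).
#' @param sampling_times Sampling times in minutes, strictly increasing,
#'   starting at 0.
#' @param duration Assay duration in minutes; defaults to the last sampling
#'   time.
#' @param detection_limit HPLC detection limit, µM; species below it report
#'   as absent. Applied only at reporting, never during integration.
#' @param phytoene_influx Zeroth-order phytoene source, µM/s (default 0;
#'   used by the in vivo phytoene-synthase surrogate).
#' @return An object of class `assay_spec`.
#' @seealso [preset_assay()] for the shipped sampling schedules.
#' @export
assay_spec <- function(initial_phytoene = 10, enzyme_total = 0.83,
                       sampling_times = c(0, 2.5, 5, 7.5, 10, 20, 30, 40, 60, 120),
                       duration = max(sampling_times),
                       detection_limit = 0.01, phytoene_influx = 0) {
  if (!is_number(initial_phytoene) || initial_phytoene < 0 ||
      (initial_phytoene == 0 && phytoene_influx <= 0)) {
    abort("`initial_phytoene` must be > 0 (or >= 0 with a positive influx)",
          "carokin_invalid_input")
  }
  if (!is_number(enzyme_total) || enzyme_total < 0) {
    abort("`enzyme_total` must be >= 0", "carokin_invalid_input")
  }
  if (!is.numeric(sampling_times) || length(sampling_times) < 1L ||
      sampling_times[1] != 0 || any(diff(sampling_times) <= 0)) {
    abort("`sampling_times` must be strictly increasing and start at 0",
          "carokin_invalid_input")
  }
  if (!is_number(detection_limit) || detection_limit < 0) {
    abort("`detection_limit` must be >= 0", "carokin_invalid_input")
  }
  if (!is_number(phytoene_influx) || phytoene_influx < 0) {
    abort("`phytoene_influx` must be >= 0", "carokin_invalid_input")
  }
  structure(list(initial_phytoene = initial_phytoene,
                 enzyme_total = enzyme_total,
                 sampling_times = as.numeric(sampling_times),
                 duration = duration,
                 detection_limit = detection_limit,
                 phytoene_influx = phytoene_influx),
            class = "assay_spec")
}

#' Preset assay designs
#'
#' The sampling schedules of the purified-enzyme kinetics experiments and
#' the crude-extract end-point assays:
#' \describe{
#'   \item{dense_schedule}{0, 2.5, 5, 7.5, 10, 20, 30, 40, 60, 120 min
#'     (10 points; used for the fast enzymes).}
#'   \item{sparse_schedule}{0, 10, 20, 40, 60, 80, 100, 120 min (8 points).}
#'   \item{crude_2h}{end point at 2 h.}
#'   \item{crude_60h}{end point at 60 h.}
#' }
#' Initial phytoene defaults to 10 µM (5 nmol in 0.5 mL); total enzyme to
#' 0.83 µM (25 µg in 0.5 mL at an assumed molar mass, see
#' `enzyme_mass_kda`).
#'
#' @param kind One of `"dense_schedule"`, `"sparse_schedule"`, `"crude_2h"`,
#'   `"crude_60h"`.
#' @param enzyme_mass_kda Assumed enzyme molar mass (kDa) for the µg to µM
#'   conversion; default 60.
#' @return An [assay_spec()].
#' @examples
#' preset_assay("dense_schedule")$sampling_times
#' @export
preset_assay <- function(kind = c("dense_schedule", "sparse_schedule",
                                  "crude_2h", "crude_60h"),
                         enzyme_mass_kda = 60) {
  kind <- match.arg(kind)
  # 25 µg in 0.5 mL: (25e-6 g / 0.5e-3 L) / (mass_kda * 1000 g/mol) * 1e6 µM
  enzyme_um <- 25 / 0.5 / enzyme_mass_kda
  enzyme_um <- round(enzyme_um, 2)
  times <- switch(kind,
    dense_schedule = c(0, 2.5, 5, 7.5, 10, 20, 30, 40, 60, 120),
    sparse_schedule = c(0, 10, 20, 40, 60, 80, 100, 120),
    crude_2h = c(0, 120),
    crude_60h = c(0, 3600)
  )
  assay_spec(initial_phytoene = 10, enzyme_total = enzyme_um,
             sampling_times = times)
}
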