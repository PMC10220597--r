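#' Registry of transcribed instrument fixtures
#'
#' Small reference tables transcribed from the published characterisation of
#' the physical platform, each row carrying a provenance string:
#'
#' * `pursing_pressure_flow`: all pressure-flow readings from the pursing
#'   rig (membrane id, MWCO, exposed diameter, pressure, flow).
#' * `pursing_12_14kDa`: the exposed-area series for the 12-14 kDa membrane
#'   at 150 mmHg (0.66 / 0.54 / 0.05 uL/min for 20 / 15 / 5 mm diameters).
#' * `pursing_mwco_at_2uLmin`: pressure drop needed for ~2.0 uL/min through
#'   a 20 mm area (361 mmHg at 12-14 kDa, 342 at 50 kDa, ~7 at 300 kDa).
#' * `calibration_standards`: the probe calibration dilution series,
#'   62.5-3.9 ug/mL.
#' * `motion_presets`: names of the shipped eye-movement programs (see
#'   [motion_preset()]).
#'
#' @param name Optional fixture name; omitted, the whole named list is
#'   returned. Unknown names are an error.
#' @return A tibble (or list of tibbles) with a `source` provenance column
#'   where applicable.
#' @examples
#' fixture_registry("pursing_mwco_at_2uLmin")
#' @export
fixture_registry <- function(name = NULL) {
  pf <- readr::read_csv(
    system.file("extdata", "pursing_pressure_flow.csv", package = "pkeyesim"),
    col_types = readr::cols(
      membrane_id = readr::col_character(),
      mwco_kda = readr::col_double(),
      exposed_diameter_mm = readr::col_double(),
      pressure_mmHg = readr::col_double(),
      flow_uL_min = readr::col_double(),
      source = readr::col_character()
    )
  )
  reg <- list(
    pursing_pressure_flow = pf,
    pursing_12_14kDa = dplyr::filter(pf, .data$mwco_kda == 13,
                                     .data$pressure_mmHg == 150),
    pursing_mwco_at_2uLmin = dplyr::filter(pf, .data$flow_uL_min == 2.0),
    calibration_standards = tibble::tibble(
      conc_ug_ml = calibration_standards(),
      source = "published probe calibration: two-fold dilutions of a 250 ug/mL labelled-albumin stock (3.9-62.5 ug/mL)"
    ),
    motion_presets = tibble::tibble(
      preset = motion_preset(),
      source = "published eye-movement platform program table"
    )
  )
  if (is.null(name)) return(reg)
  if (!name %in% names(reg)) {
    pkeye_stop(sprintf("Unknown fixture '%s'. Available: %s.",
                       name, paste(names(reg), collapse = ", ")),
               "pkeye_key_error")
  }
  reg[[name]]
}

#' Derive a reproducible sub-seed for a named module stream
#'
#' Every stochastic operation accepts an explicit seed. To keep module
#' streams independent of one another, a run seed is combined with a stable
#' stream label so that adding draws in one module never perturbs another's.
#' The derivation is a fixed integer hash, always below 2^31.
#'
#' @param seed Integer run seed.
#' @param label Stream label, e.g. `"probe"` or `"flow_sensor"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "probe")
#' @export
derive_seed <- function(seed, label) {
  check_number(seed, "seed")
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(seed) * 48271 + h * 7919) %% (2^31 - 1))
}
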