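# Registered telemetry units. Channels outside this set are rejected at
# read and write time so files stay self-describing.
TELEMETRY_UNITS <- c("mmHg", "uL_min", "degC", "m_s2", "deg", "deg_s", "ug_mL")

# Platform recording limits: one acquisition chain supports at most 6
# controllers x 6 flow sensors logged at up to 50 Hz per channel (1800
# points per second fully populated).
MAX_RECORDING_HZ <- 50
MAX_CONTROLLERS <- 6
MAX_SENSORS_PER_CONTROLLER <- 6

#' Registered telemetry units
#'
#' @return Character vector of the unit labels accepted in telemetry frames.
#' @export
telemetry_units <- function() TELEMETRY_UNITS

#' Validate a telemetry frame table
#'
#' Telemetry is exchanged as long-format frames: one row per (time, channel)
#' observation with an explicit unit, which keeps channels sampled at
#' different rates in a single file.
#'
#' @param frames Data frame with columns `time_s`, `channel`, `value`,
#'   `unit`.
#' @return The frames as a tibble, invisibly validated.
#' @export
as_telemetry <- function(frames) {
  stopifnot(is.data.frame(frames))
  need <- c("time_s", "channel", "value", "unit")
  if (!all(need %in% names(frames))) {
    pkeye_stop(sprintf("Telemetry frames need columns %s.", paste(need, collapse = ", ")),
               "pkeye_schema_error")
  }
  frames <- tibble::as_tibble(frames)[need]
  bad <- which(!frames$unit %in% TELEMETRY_UNITS)
  if (length(bad) > 0) {
    pkeye_stop(sprintf("Unknown unit '%s' in telemetry row %d (registered: %s).",
                       frames$unit[bad[1]], bad[1],
                       paste(TELEMETRY_UNITS, collapse = ", ")),
               "pkeye_schema_error")
  }
  if (nrow(frames) > 0 && any(frames$time_s < 0)) {
    pkeye_stop("Telemetry times must be non-negative.", "pkeye_schema_error")
  }
  frames
}

#' Write and read telemetry CSV files
#'
#' The on-disk dialect is a long-format CSV with header
#' `time_s,channel,value,unit`. Numeric values are rendered with 9
#' significant digits; a write/read round trip is lossless under that
#' rendering contract. Reading validates the unit column and reports the
#' first offending line.
#'
#' @param frames Telemetry frames (see [as_telemetry()]).
#' @param path File path.
#' @return `write_telemetry()` returns `path` invisibly; `read_telemetry()`
#'   returns a validated telemetry tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_telemetry(tibble::tibble(time_s = 0, channel = "pressure",
#'                                value = 15, unit = "mmHg"), f)
#' read_telemetry(f)
#' @export
write_telemetry <- function(frames, path) {
  frames <- as_telemetry(frames)
  out <- data.frame(
    time_s = sprintf("%.9g", frames$time_s),
    channel = frames$channel,
    value = sprintf("%.9g", frames$value),
    unit = frames$unit
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_telemetry
#' @export
read_telemetry <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), channel = readr::col_character(),
    value = readr::col_double(), unit = readr::col_character()
  ))
  bad <- which(!raw$unit %in% TELEMETRY_UNITS)
  if (length(bad) > 0) {
    pkeye_stop(sprintf("Unknown unit '%s' at line %d of %s.",
                       raw$unit[bad[1]], bad[1] + 1L, path),
               "pkeye_schema_error")
  }
  as_telemetry(raw)
}

#' Acquisition-plan configuration and validation
#'
#' A run configuration fixes the random seed and the telemetry plan. The
#' validator enforces the acquisition chain's hard limits: at most 50 Hz per
#' channel, 6 controllers, and 6 flow sensors per controller.
#'
#' @param seed Integer run seed.
#' @param recording_rate_hz Per-channel recording rate, Hz (default 1).
#' @param controllers Number of pressure controllers (1-6).
#' @param sensors_per_controller Flow sensors per controller (1-6).
#' @return An object of class `run_config`.
#' @examples
#' max_throughput(run_config(seed = 1, recording_rate_hz = 50,
#'                           controllers = 6, sensors_per_controller = 6))
#' @export
run_config <- function(seed = 1, recording_rate_hz = 1, controllers = 1,
                       sensors_per_controller = 1) {
  check_number(seed, "seed")
  check_number(recording_rate_hz, "recording_rate_hz", min = 0, strict_min = TRUE,
               max = MAX_RECORDING_HZ, class = "pkeye_validation_error")
  check_number(controllers, "controllers", min = 1, max = MAX_CONTROLLERS,
               class = "pkeye_validation_error")
  check_number(sensors_per_controller, "sensors_per_controller", min = 1,
               max = MAX_SENSORS_PER_CONTROLLER, class = "pkeye_validation_error")
  structure(list(seed = as.integer(seed), recording_rate_hz = recording_rate_hz,
                 controllers = as.integer(controllers),
                 sensors_per_controller = as.integer(sensors_per_controller)),
            class = "run_config")
}

#' Maximum telemetry throughput of an acquisition plan
#'
#' @param config A [run_config()].
#' @return Data points per second: `rate * controllers * sensors`; the fully
#'   populated chain (50 Hz x 6 x 6) yields 1800.
#' @export
max_throughput <- function(config) {
  stopifnot(inherits(config, "run_config"))
  config$recording_rate_hz * config$controllers * config$sensors_per_controller
}
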