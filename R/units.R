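# Exact conversion constants used at every interface boundary. Internals of
# the hydraulic forward model run in SI (Pa, m^3/s); user-facing functions
# accept and emit mmHg and uL/min.

#' Unit conversions between interface and SI hydraulic units
#'
#' The simulator computes membrane hydraulics in SI units (Pa, m^3/s) and
#' exposes interfaces in the units printed on the instrument: mmHg for
#' pressure and uL/min for flow. Conversions are exact:
#' 1 mmHg = 133.322 Pa and 1 uL/min = 1/6e10 m^3/s.
#'
#' @param x Numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' mmHg_to_pa(150)
#' m3s_to_ulmin(ulmin_to_m3s(2))
#' @name units
NULL

MMHG_PER_PA <- 1 / 133.322
PA_PER_MMHG <- 133.322
M3S_PER_ULMIN <- 1e-9 / 60

#' @rdname units
#' @export
mmHg_to_pa <- function(x) x * PA_PER_MMHG

#' @rdname units
#' @export
pa_to_mmHg <- function(x) x * MMHG_PER_PA

#' @rdname units
#' @export
ulmin_to_m3s <- function(x) x * M3S_PER_ULMIN

#' @rdname units
#' @export
m3s_to_ulmin <- function(x) x / M3S_PER_ULMIN

# internal: classed abort so callers can distinguish failure modes
pkeye_stop <- function(message, class) {
  rlang::abort(message, class = c(class, "pkeye_error"))
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE,
                         class = "pkeye_invalid_parameter") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    pkeye_stop(sprintf("`%s` must be a single finite number.", name), class)
  }
  lo_bad <- if (strict_min) x <= min else x < min
  hi_bad <- if (strict_max) x >= max else x > max
  if (lo_bad || hi_bad) {
    pkeye_stop(sprintf(
      "`%s` = %g is outside the admissible range %s%g, %g%s.",
      name, x, if (strict_min) "(" else "[", min, max,
      if (strict_max) ")" else "]"
    ), class)
  }
  invisible(x)
}
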