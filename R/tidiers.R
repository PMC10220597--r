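#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fitted pkeyesim objects
#'
#' broom-style accessors: `tidy()` returns per-observation or per-term rows,
#' `glance()` a one-row model summary.
#'
#' @param x A `pore_radius_fit`, `half_life_fit`, `calibration_fit` or
#'   `clearance_sim`.
#' @param ... Unused.
#' @return A tibble.
#' @name pkeyesim-tidiers
NULL

#' @rdname pkeyesim-tidiers
#' @export
tidy.pore_radius_fit <- function(x, ...) x$residuals

#' @rdname pkeyesim-tidiers
#' @export
glance.pore_radius_fit <- function(x, ...) {
  tibble::tibble(
    pore_radius_m = x$pore_radius_m,
    pore_radius_nm = x$pore_radius_m * 1e9,
    rel_rmse = sqrt(mean(x$residuals$rel_error^2)),
    n = nrow(x$residuals)
  )
}

#' @rdname pkeyesim-tidiers
#' @export
tidy.half_life_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2])
}

#' @rdname pkeyesim-tidiers
#' @export
glance.half_life_fit <- function(x, ...) {
  tibble::tibble(half_life_days = x$half_life_days,
                 slope_per_day = x$slope_per_day,
                 r_squared = x$r_squared, n = x$n)
}

#' @rdname pkeyesim-tidiers
#' @export
tidy.calibration_fit <- function(x, ...) x$standards

#' @rdname pkeyesim-tidiers
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = nrow(x$standards))
}

#' @rdname pkeyesim-tidiers
#' @export
tidy.clearance_sim <- function(x, ...) {
  tidyr::pivot_longer(x$traces, -"time_s",
                      names_to = "series", values_to = "value")
}

#' @rdname pkeyesim-tidiers
#' @export
glance.clearance_sim <- function(x, ...) {
  tibble::tibble(
    prototype = x$model$prototype,
    dose_ug = x$drug$dose_mass_ug,
    duration_days = max(x$traces$time_s) / 86400,
    half_life_days = if (!is.null(x$half_life)) x$half_life$half_life_days else NA_real_,
    fit_r_squared = if (!is.null(x$half_life)) x$half_life$r_squared else NA_real_,
    fraction_cleared = (dplyr::last(x$traces$cleared_anterior_ug) +
                          dplyr::last(x$traces$cleared_posterior_ug)) /
      max(x$drug$dose_mass_ug, .Machine$double.eps),
    mass_balance_rel_err = x$mass_balance_rel_err
  )
}
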