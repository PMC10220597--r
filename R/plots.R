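#' Plot methods for pkeyesim result objects
#'
#' ggplot2 `autoplot()` methods: concentration-time curves for clearance
#' simulations (log concentration axis), angle and velocity panels for eye
#' trajectories, observed-vs-fitted lines for calibration fits, and the
#' staircase for pressure sweeps via [plot_telemetry()].
#'
#' @param object A `clearance_sim`, `eye_trajectory` or `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pkeyesim-autoplot
NULL

#' @rdname pkeyesim-autoplot
#' @export
autoplot.clearance_sim <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object$traces, "time_s", dplyr::starts_with("conc_")),
    -"time_s", names_to = "compartment", values_to = "conc_ug_ml"
  )
  d <- dplyr::filter(d, .data$conc_ug_ml > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s / 86400, .data$conc_ug_ml,
                                  colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "concentration (ug/mL)",
                  title = sprintf("Clearance, %s prototype", object$model$prototype))
}

#' @rdname pkeyesim-autoplot
#' @export
autoplot.eye_trajectory <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object, "time_s", "angle_deg", "velocity_deg_s"),
    -"time_s", names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @rdname pkeyesim-autoplot
#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$standards, ggplot2::aes(.data$conc_ug_ml, .data$auc)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "concentration (ug/mL)", y = "signal AUC",
                  title = sprintf("Probe calibration (R^2 = %.4f)", object$r_squared))
}

#' Plot long-format telemetry frames
#'
#' @param frames Telemetry frames (columns `time_s`, `channel`, `value`,
#'   `unit`).
#' @return A ggplot object, one facet per channel.
#' @export
plot_telemetry <- function(frames) {
  frames <- as_telemetry(frames)
  ggplot2::ggplot(frames, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
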