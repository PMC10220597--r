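#' Virtual fluorescence concentration probe
#'
#' Configuration of the flow-cell fluorescence probe: a labelled protein
#' passing the cell excited at 470 nm produces an emission signal whose area
#' under the curve (AUC) within a fixed 250 ms integration window is linear
#' in concentration. The absolute response factor of the physical instrument
#' is not published, so the probe carries a configurable gain
#' (`response_factor`, default 1000 AUC per ug/mL); only linearity and
#' round-trip properties are meaningful, never absolute AUC values.
#'
#' Two noise scales are distinguished: `noise_sd_ug_ml` is the per-reading
#' noise of a routed concentration measurement (default 0.05 ug/mL, which
#' keeps successive one-minute readings on a smooth clearance trace within
#' the observed < 0.3 ug/mL band), and `calibration_noise_sd_ug_ml` the
#' reading noise during calibration (default 1.0 ug/mL-equivalent, giving
#' calibration fits with R^2 in [0.99, 1)). An optional outlier process
#' (probability `outlier_prob`, magnitude `outlier_scale` times the reading)
#' models out-of-range readings; off by default.
#'
#' @param excitation_nm Excitation wavelength, nm (metadata; default 470).
#' @param integration_window_ms Signal integration window, ms; > 0 (default
#'   250).
#' @param read_interval_s Spacing of probe readings, s; must be at least the
#'   integration window (default 60, one reading per minute).
#' @param noise_sd_ug_ml Reading noise SD, ug/mL-equivalent.
#' @param calibration_noise_sd_ug_ml Calibration reading noise SD,
#'   ug/mL-equivalent.
#' @param response_factor Probe gain, AUC per (ug/mL); > 0.
#' @param outlier_prob,outlier_scale Out-of-range reading process.
#' @return An object of class `probe_config`.
#' @examples
#' probe_config()
#' @export
probe_config <- function(excitation_nm = 470, integration_window_ms = 250,
                         read_interval_s = 60, noise_sd_ug_ml = 0.05,
                         calibration_noise_sd_ug_ml = 1.0,
                         response_factor = 1000,
                         outlier_prob = 0, outlier_scale = 3) {
  check_number(integration_window_ms, "integration_window_ms", min = 0, strict_min = TRUE)
  check_number(read_interval_s, "read_interval_s", min = integration_window_ms / 1000)
  check_number(noise_sd_ug_ml, "noise_sd_ug_ml", min = 0)
  check_number(calibration_noise_sd_ug_ml, "calibration_noise_sd_ug_ml", min = 0)
  check_number(response_factor, "response_factor", min = 0, strict_min = TRUE)
  check_number(outlier_prob, "outlier_prob", min = 0, max = 1)
  structure(list(excitation_nm = excitation_nm,
                 integration_window_ms = integration_window_ms,
                 read_interval_s = read_interval_s,
                 noise_sd_ug_ml = noise_sd_ug_ml,
                 calibration_noise_sd_ug_ml = calibration_noise_sd_ug_ml,
                 response_factor = response_factor,
                 outlier_prob = outlier_prob, outlier_scale = outlier_scale),
            class = "probe_config")
}

#' Default calibration standards
#'
#' The two-fold dilution series of the labelled-albumin stock (250 ug/mL)
#' used to calibrate the probe: 62.5 down to about 3.9 ug/mL.
#'
#' @return Numeric vector of standard concentrations, ug/mL.
#' @export
calibration_standards <- function() 250 / 2^(2:6)

#' Fit a probe calibration curve
#'
#' Simulates one probe reading per standard (concentration plus calibration
#' noise, scaled by the response factor) and fits the AUC on concentration by
#' ordinary least squares. With zero noise the fit is exact (R^2 = 1); at the
#' default noise the R^2 is comparable to the ~0.994 obtained on the physical
#' instrument.
#'
#' @param standards Standard concentrations, ug/mL; at least 3 distinct
#'   values (default [calibration_standards()]).
#' @param probe A [probe_config()].
#' @param seed Optional integer seed for the reading noise.
#' @param auc Optional vector of measured AUCs (one per standard); when
#'   supplied no readings are simulated.
#' @return An object of class `calibration_fit`: `slope` (AUC per ug/mL),
#'   `intercept` (AUC), `r_squared`, `standards` (tibble of concentration,
#'   AUC) and the `lm` fit. Has `tidy()`, `glance()` and `autoplot()`
#'   methods.
#' @examples
#' fit <- fit_calibration(seed = 1)
#' glance(fit)
#' @export
fit_calibration <- function(standards = calibration_standards(),
                            probe = probe_config(), seed = NULL, auc = NULL) {
  if (length(unique(standards)) < 3) {
    pkeye_stop("Calibration needs at least 3 distinct standard concentrations.",
               "pkeye_fitting_error")
  }
  if (any(standards < 0)) {
    pkeye_stop("Standard concentrations must be >= 0.", "pkeye_invalid_parameter")
  }
  if (is.null(auc)) {
    if (!is.null(seed)) set.seed(seed)
    eps <- if (probe$calibration_noise_sd_ug_ml > 0)
      stats::rnorm(length(standards), 0, probe$calibration_noise_sd_ug_ml) else 0
    auc <- probe$response_factor * (standards + eps)
  } else if (length(auc) != length(standards)) {
    pkeye_stop("`auc` must be one reading per standard.", "pkeye_fitting_error")
  }
  d <- tibble::tibble(conc_ug_ml = standards, auc = auc)
  fit <- stats::lm(auc ~ conc_ug_ml, data = d)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit))$r.squared,
    standards = d,
    fit = fit
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> AUC = %.4g * C + %.4g (R^2 = %.4f, %d standards)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' Convert probe signal AUC to concentration
#'
#' Inverts the linear calibration: `C = (AUC - intercept) / slope`. Noisy
#' blank readings can fall below the intercept; these are clipped to zero and
#' flagged.
#'
#' @param auc Numeric vector of signal AUCs.
#' @param fit A [fit_calibration()] result; its slope must be > 0.
#' @return Tibble with columns `auc`, `conc_ug_ml` (>= 0), `clipped`.
#' @examples
#' fit <- fit_calibration(probe = probe_config(calibration_noise_sd_ug_ml = 0))
#' auc_to_concentration(10 * fit$slope + fit$intercept, fit)
#' @export
auc_to_concentration <- function(auc, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    pkeye_stop("Calibration slope must be > 0 to invert the curve.",
               "pkeye_calibration_error")
  }
  conc <- (auc - fit$intercept) / fit$slope
  tibble::tibble(auc = auc, conc_ug_ml = pmax(conc, 0), clipped = conc < 0)
}

#' Route inlet streams through the valve multiplexer and sample the probe
#'
#' Emulates the valve platform (a bank of 3-port/2-way switches feeding an
#' 11-port rotary selector) that routes exactly one inlet at a time to the
#' single concentration probe. During windows routed to a known inlet the
#' probe takes one reading every `read_interval_s` (interpolated inlet
#' concentration plus reading noise, floored at zero); windows routed to
#' `"waste"` produce no probe samples. The selector outflow equals the
#' routed inlet's flow at every instant (zero while routed to waste).
#'
#' @param inlets Long-format tibble of inlet traces with columns `route`
#'   (inlet label), `time_s`, `conc_ug_ml` and optionally `flow_uL_min`.
#'   Every scheduled route other than `"waste"` must appear here.
#' @param schedule A [build_switch_schedule()] result; its horizon must not
#'   exceed the inlet trace span.
#' @param probe A [probe_config()].
#' @param seed Optional integer seed for the reading noise.
#' @return List of class `probe_run`: `probe_trace` (tibble `time_s`,
#'   `route`, `conc_ug_ml`, `flag`) and `outflow` (tibble `time_s`, `route`,
#'   `flow_uL_min` sampled at the read interval).
#' @examples
#' inl <- tibble::tibble(route = "model_1", time_s = c(0, 3600),
#'                       conc_ug_ml = c(10, 8), flow_uL_min = 2)
#' sch <- build_switch_schedule("round_robin", horizon_s = 3600,
#'                              dwell_s = 600, inlets = "model_1")
#' run <- route_and_sample(inl, sch, probe_config(noise_sd_ug_ml = 0))
#' @export
route_and_sample <- function(inlets, schedule, probe = probe_config(), seed = NULL) {
  stopifnot(is.data.frame(inlets), inherits(schedule, "switch_schedule"))
  stopifnot(all(c("route", "time_s", "conc_ug_ml") %in% names(inlets)))
  horizon <- attr(schedule, "horizon_s")
  span <- range(inlets$time_s)
  if (horizon > span[2] - span[1] + 1e-9) {
    pkeye_stop("Schedule horizon exceeds the inlet trace span.",
               "pkeye_routing_error")
  }
  routes_needed <- setdiff(unique(schedule$route), "waste")
  missing <- setdiff(routes_needed, unique(inlets$route))
  if (length(missing) > 0) {
    pkeye_stop(sprintf("Scheduled route(s) absent from inlets: %s.",
                       paste(missing, collapse = ", ")), "pkeye_routing_error")
  }
  if (!is.null(seed)) set.seed(seed)

  win <- schedule_windows(schedule)
  conc_funs <- lapply(split(inlets, inlets$route), function(d) {
    if (nrow(d) == 1) {
      cf <- function(t) rep(d$conc_ug_ml, length(t))
      ff <- function(t) rep(if ("flow_uL_min" %in% names(d)) d$flow_uL_min else NA_real_, length(t))
    } else {
      cf <- stats::approxfun(d$time_s, d$conc_ug_ml, rule = 2)
      ff <- if ("flow_uL_min" %in% names(d))
        stats::approxfun(d$time_s, d$flow_uL_min, rule = 2) else function(t) rep(NA_real_, length(t))
    }
    list(conc = cf, flow = ff)
  })

  probe_rows <- list()
  flow_rows <- list()
  for (i in seq_len(nrow(win))) {
    rt <- win$route[i]
    t <- seq(win$start_s[i], win$end_s[i] - 1e-9, by = probe$read_interval_s)
    if (length(t) == 0) next
    if (rt == "waste") {
      flow_rows[[i]] <- tibble::tibble(time_s = t, route = rt, flow_uL_min = 0)
      next
    }
    f <- conc_funs[[rt]]
    conc <- f$conc(t)
    if (probe$noise_sd_ug_ml > 0) conc <- conc + stats::rnorm(length(t), 0, probe$noise_sd_ug_ml)
    flag <- rep("ok", length(t))
    if (probe$outlier_prob > 0) {
      out <- stats::runif(length(t)) < probe$outlier_prob
      conc[out] <- conc[out] * probe$outlier_scale
      flag[out] <- "out_of_range"
    }
    flag[conc < 0] <- "clipped"
    probe_rows[[i]] <- tibble::tibble(time_s = t, route = rt,
                                      conc_ug_ml = pmax(conc, 0), flag = flag)
    flow_rows[[i]] <- tibble::tibble(time_s = t, route = rt, flow_uL_min = f$flow(t))
  }
  empty_probe <- tibble::tibble(time_s = numeric(), route = character(),
                                conc_ug_ml = numeric(), flag = character())
  probe_trace <- dplyr::bind_rows(probe_rows)
  if (nrow(probe_trace) == 0) probe_trace <- empty_probe
  structure(list(
    probe_trace = probe_trace,
    outflow = dplyr::bind_rows(flow_rows),
    schedule = schedule
  ), class = "probe_run")
}

#' @export
print.probe_run <- function(x, ...) {
  cat(sprintf("<probe_run> %d probe readings over %d schedule windows\n",
              nrow(x$probe_trace), nrow(schedule_windows(x$schedule))))
  invisible(x)
}

#' Reconstruct a gapped concentration-time profile
#'
#' A duty-cycled probe sees the clearance curve only during its sampling
#' windows. This groups a probe trace into windows by time adjacency (a gap
#' longer than `gap_factor` read intervals starts a new window) and
#' summarises each: mean concentration, mid-time, sample count and the
#' maximum successive-sample difference (the smoothness statistic used to
#' judge probe stability).
#'
#' @param trace Probe trace tibble with columns `time_s`, `conc_ug_ml`
#'   (non-empty).
#' @param read_interval_s Nominal reading spacing, s; default the median
#'   spacing of the trace.
#' @param gap_factor Multiples of the read interval that constitute a gap
#'   (default 2).
#' @return Tibble with one row per window: `window`, `t_start_s`, `t_end_s`,
#'   `t_mid_s`, `n`, `mean_conc_ug_ml`, `max_step_ug_ml`; the gap lengths
#'   between consecutive windows are attached as attribute `gaps_s`.
#' @export
reconstruct_profile <- function(trace, read_interval_s = NULL, gap_factor = 2) {
  stopifnot(is.data.frame(trace), all(c("time_s", "conc_ug_ml") %in% names(trace)))
  if (nrow(trace) == 0) {
    pkeye_stop("Cannot reconstruct from an empty trace.", "pkeye_empty_trace_error")
  }
  trace <- dplyr::arrange(trace, .data$time_s)
  dt <- diff(trace$time_s)
  if (is.null(read_interval_s)) {
    read_interval_s <- if (length(dt) > 0) stats::median(dt) else 1
  }
  window <- cumsum(c(1, as.integer(dt > gap_factor * read_interval_s)))
  out <- trace |>
    dplyr::mutate(window = window) |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(
      t_start_s = min(.data$time_s),
      t_end_s = max(.data$time_s),
      t_mid_s = (min(.data$time_s) + max(.data$time_s)) / 2,
      n = dplyr::n(),
      mean_conc_ug_ml = mean(.data$conc_ug_ml),
      max_step_ug_ml = if (dplyr::n() > 1) max(abs(diff(.data$conc_ug_ml))) else 0,
      .groups = "drop"
    )
  attr(out, "gaps_s") <- if (nrow(out) > 1)
    out$t_start_s[-1] - out$t_end_s[-nrow(out)] else numeric()
  out
}
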