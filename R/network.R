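#' Build a table of hydraulic branches
#'
#' A branch is the lumped resistance of one eye model plus its tubing and
#' sensor, expressed in mmHg per (uL/min). A single pressure source feeding
#' several branches in parallel sees the same pressure on every branch while
#' the flow divides between them -- the property that lets one pump drive up
#' to six models simultaneously.
#'
#' @param resistance Numeric vector of branch resistances, mmHg per (uL/min);
#'   all > 0.
#' @param label Optional branch labels (default `model_1..model_n`).
#' @return Tibble with columns `label`, `resistance`.
#' @examples
#' hydraulic_branches(c(9, 9, 9))
#' @export
hydraulic_branches <- function(resistance, label = NULL) {
  if (length(resistance) < 1 || any(!is.finite(resistance)) || any(resistance <= 0)) {
    pkeye_stop("`resistance` must be a non-empty vector of positive numbers.",
               "pkeye_configuration_error")
  }
  if (is.null(label)) label <- paste0("model_", seq_along(resistance))
  tibble::tibble(label = as.character(label), resistance = as.numeric(resistance))
}

#' Solve a parallel network driven by one pressure source
#'
#' In a pressure-controlled parallel network every branch sees the source
#' pressure, so each branch flow is the Ohmic analogue `Q_i = P / R_i` and
#' the source supplies the sum of the branch flows.
#'
#' @param source_pressure_mmHg Source pressure, mmHg; >= 0.
#' @param branches Tibble from [hydraulic_branches()] (columns `label`,
#'   `resistance`); at least one branch.
#' @return Tibble with columns `label`, `resistance`, `flow_uL_min`; the
#'   total source flow is attached as attribute `total_flow_uL_min`.
#' @examples
#' solve_parallel(10, hydraulic_branches(c(1, 2)))
#' @export
solve_parallel <- function(source_pressure_mmHg, branches) {
  check_number(source_pressure_mmHg, "source_pressure_mmHg", min = 0)
  if (!is.data.frame(branches) || nrow(branches) < 1 ||
      !all(c("label", "resistance") %in% names(branches))) {
    pkeye_stop("`branches` must be a non-empty tibble with columns label, resistance.",
               "pkeye_configuration_error")
  }
  if (any(branches$resistance <= 0)) {
    pkeye_stop("Branch resistances must be > 0.", "pkeye_configuration_error")
  }
  out <- dplyr::mutate(tibble::as_tibble(branches),
                       flow_uL_min = source_pressure_mmHg / .data$resistance)
  attr(out, "total_flow_uL_min") <- sum(out$flow_uL_min)
  out
}

#' Simulate pressure- or flow-controlled operation of a branch network
#'
#' Two control modes mirror the physical platform. In pressure mode the
#' source pressure is held at the setpoint and every parallel branch flows at
#' `P/R_i` (any number of branches). In flow mode the controller adjusts
#' pressure until the measured flow matches the setpoint -- physically
#' possible only with a single branch, because flow divides in parallel;
#' settling is modelled as first order with time constant `tau_s`.
#'
#' @param branches Tibble from [hydraulic_branches()].
#' @param mode `"pressure"` or `"flow"`.
#' @param setpoint Setpoint: mmHg in pressure mode, uL/min in flow mode.
#' @param duration_s Simulated duration, s.
#' @param sample_rate_hz Recording rate, Hz (default 1, the platform's
#'   logging rate).
#' @param pressure_noise_sd,flow_noise_sd Gaussian sensor noise SDs (mmHg,
#'   uL/min).
#' @param tau_s Flow-controller settling time constant, s (default 60).
#' @param seed Optional integer seed.
#' @return Long-format telemetry tibble with columns `time_s`, `channel`,
#'   `value`, `unit`; channels are `pressure` and `flow_<label>`.
#' @examples
#' simulate_controller(hydraulic_branches(9), "flow", 2, duration_s = 10)
#' @export
simulate_controller <- function(branches, mode = c("pressure", "flow"), setpoint,
                                duration_s, sample_rate_hz = 1,
                                pressure_noise_sd = 0, flow_noise_sd = 0,
                                tau_s = 60, seed = NULL) {
  mode <- match.arg(mode)
  check_number(setpoint, "setpoint", min = 0)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(pressure_noise_sd, "pressure_noise_sd", min = 0)
  check_number(flow_noise_sd, "flow_noise_sd", min = 0)
  if (!is.data.frame(branches) || nrow(branches) < 1) {
    pkeye_stop("`branches` must be a non-empty branch table.", "pkeye_configuration_error")
  }
  if (mode == "flow" && nrow(branches) != 1) {
    pkeye_stop("Flow control is only possible with exactly one branch: flow divides in a parallel network, so only pressure can drive several models at once.",
               "pkeye_mode_error")
  }
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s, by = 1 / sample_rate_hz)
  n <- length(t)

  if (mode == "pressure") {
    pressure <- rep(setpoint, n)
    flows <- lapply(seq_len(nrow(branches)), function(i) setpoint / branches$resistance[i])
    flows <- lapply(flows, rep, n)
  } else {
    q <- setpoint * (1 - exp(-t / tau_s))
    pressure <- q * branches$resistance[1]
    flows <- list(q)
  }

  noisy <- function(x, sd) if (sd > 0) x + stats::rnorm(length(x), 0, sd) else x
  frames <- list(tibble::tibble(
    time_s = t, channel = "pressure",
    value = noisy(pressure, pressure_noise_sd), unit = "mmHg"
  ))
  for (i in seq_len(nrow(branches))) {
    frames[[i + 1]] <- tibble::tibble(
      time_s = t, channel = paste0("flow_", branches$label[i]),
      value = noisy(flows[[i]], flow_noise_sd), unit = "uL_min"
    )
  }
  dplyr::bind_rows(frames)
}

#' Circadian aqueous-flow program
#'
#' Aqueous humour secretion follows a diurnal rhythm, roughly 3.0 uL/min in
#' the morning down to 1.5 uL/min at night. The platform reproduces it as a
#' sinusoid between the two bounds over a 24 h period. The trace mean over an
#' integer number of periods equals the midpoint `(min + max)/2`.
#'
#' @param min_flow,max_flow Flow bounds, uL/min; `max_flow >= min_flow > 0`.
#' @param period_s Period, s (default 24 h).
#' @param peak_time_s Clock time (seconds after midnight) of the flow
#'   maximum; default 08:00, since the maximum occurs in the morning.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param duration_s Trace duration, s; must cover at least one sample.
#' @param start_time_s Clock time of the first sample (default midnight).
#' @return Tibble with columns `time_s`, `flow_uL_min`.
#' @examples
#' prog <- circadian_program(1.5, 3.0, duration_s = 86400, sample_rate_hz = 1/60)
#' range(prog$flow_uL_min)
#' @export
circadian_program <- function(min_flow = 1.5, max_flow = 3.0,
                              period_s = 86400, peak_time_s = 8 * 3600,
                              sample_rate_hz = 1, duration_s = 86400,
                              start_time_s = 0) {
  check_number(min_flow, "min_flow", min = 0, strict_min = TRUE)
  check_number(max_flow, "max_flow", min = min_flow)
  check_number(period_s, "period_s", min = 0, strict_min = TRUE)
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  if (duration_s < 1 / sample_rate_hz) {
    pkeye_stop("`duration_s` is shorter than one sampling interval; the trace would be empty.",
               "pkeye_empty_trace_error")
  }
  t <- start_time_s + seq(0, duration_s - 1 / sample_rate_hz, by = 1 / sample_rate_hz)
  mid <- (min_flow + max_flow) / 2
  amp <- (max_flow - min_flow) / 2
  tibble::tibble(
    time_s = t - start_time_s,
    flow_uL_min = mid + amp * cos(2 * pi * (t - peak_time_s) / period_s)
  )
}

#' Detect leak and blockage events in pressure-flow telemetry
#'
#' Quality control for a running model: a leak shows up as the model pressure
#' collapsing towards zero while the imposed flow is unaltered (fluid escapes
#' without back-pressure); a blockage shows up as a pressure spike well above
#' baseline. Detection compares centred rolling medians against the
#' channel-wide median baseline: a leak is flagged where the windowed median
#' pressure falls below `leak_pressure_threshold` while the windowed median
#' flow stays within +/-20% of its baseline; a blockage where the windowed
#' median pressure exceeds `spike_factor` times the baseline pressure.
#' Contiguous flagged samples merge into one event reported at onset.
#'
#' @param pressure Either a tibble with columns `time_s`, `pressure_mmHg` and
#'   `flow_uL_min`, or a tibble `time_s`,`value` when `flow` is given
#'   separately.
#' @param flow Optional tibble `time_s`,`value` with flow in uL/min; its
#'   timestamps must match `pressure` exactly.
#' @param leak_pressure_threshold Pressure below which a leak is suspected,
#'   mmHg (default 2).
#' @param spike_factor Multiple of baseline pressure flagged as blockage
#'   (default 2).
#' @param window_s Rolling-median window, s (default 300).
#' @return Tibble of events: `kind` ("leak" or "blockage"), `time_s` (onset),
#'   `pressure_mmHg`, `flow_uL_min` (windowed medians at onset). Zero rows
#'   when the trace is clean.
#' @examples
#' tr <- tibble::tibble(time_s = 0:999, pressure_mmHg = 15, flow_uL_min = 2)
#' detect_qc_events(tr)
#' @export
detect_qc_events <- function(pressure, flow = NULL,
                             leak_pressure_threshold = 2,
                             spike_factor = 2, window_s = 300) {
  if (!is.null(flow)) {
    if (!identical(pressure$time_s, flow$time_s)) {
      pkeye_stop("Pressure and flow traces have mismatched timestamps.",
                 "pkeye_alignment_error")
    }
    trace <- tibble::tibble(time_s = pressure$time_s,
                            pressure_mmHg = pressure$value,
                            flow_uL_min = flow$value)
  } else {
    stopifnot(all(c("time_s", "pressure_mmHg", "flow_uL_min") %in% names(pressure)))
    trace <- pressure
  }
  n <- nrow(trace)
  if (n < 3) return(qc_empty())

  dt <- stats::median(diff(trace$time_s))
  k <- max(3L, floor(window_s / dt))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (n %% 2 == 1) n else n - 1L)

  med_p <- stats::runmed(trace$pressure_mmHg, k, endrule = "median")
  med_q <- stats::runmed(trace$flow_uL_min, k, endrule = "median")
  base_p <- stats::median(trace$pressure_mmHg)
  base_q <- stats::median(trace$flow_uL_min)

  leak <- med_p < leak_pressure_threshold & abs(med_q - base_q) <= 0.2 * abs(base_q)
  block <- med_p > spike_factor * base_p

  onset_events <- function(flag, kind) {
    if (!any(flag)) return(qc_empty())
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- starts[r$values]
    tibble::tibble(kind = kind, time_s = trace$time_s[idx],
                   pressure_mmHg = med_p[idx], flow_uL_min = med_q[idx])
  }
  out <- dplyr::bind_rows(onset_events(leak, "leak"), onset_events(block, "blockage"))
  dplyr::arrange(out, .data$time_s)
}

qc_empty <- function() {
  tibble::tibble(kind = character(), time_s = numeric(),
                 pressure_mmHg = numeric(), flow_uL_min = numeric())
}
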