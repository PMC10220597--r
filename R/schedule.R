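#' Build a valve switch schedule
#'
#' Schedules describe which inlet the rotary selector routes to the
#' concentration probe at each moment; they tile the horizon `[0, horizon)`
#' exactly, with no gaps or overlaps, starting at t = 0. Three kinds mirror
#' the programs run on the physical valve platform:
#'
#' * `round_robin`: cycle `inlets` in order with a fixed dwell -- e.g. three
#'   inlets visited every 10 min for an hour gives 6 dwell windows 1,2,3,1,2,3.
#' * `alternating`: alternate between a model outlet and a reference (blank
#'   buffer) line with a fixed dwell (e.g. every 2 h).
#' * `duty_cycle`: route the model to the probe for `on_s`, then to waste for
#'   `off_s` -- e.g. 20 min through the probe every 4 h 40 min, leaving
#'   280-min gaps in the recorded profile.
#'
#' @param kind `"round_robin"`, `"alternating"` or `"duty_cycle"`.
#' @param horizon_s Schedule horizon, s; > 0.
#' @param dwell_s Dwell per window (round_robin, alternating), s; > 0.
#' @param inlets Character vector of inlet labels (round_robin).
#' @param routes Length-2 labels for alternating (default `model_1`,
#'   `reference`).
#' @param on_s,off_s Probe/waste durations for duty_cycle, s; `on_s` > 0.
#' @return Tibble of class `switch_schedule` with columns `time_s`, `route`
#'   (one row per switch event, first at 0), attribute `horizon_s`.
#' @examples
#' build_switch_schedule("round_robin", horizon_s = 3600, dwell_s = 600,
#'                       inlets = c("model_1", "model_2", "model_3"))
#' build_switch_schedule("duty_cycle", horizon_s = 25 * 3600,
#'                       on_s = 20 * 60, off_s = 280 * 60)
#' @export
build_switch_schedule <- function(kind = c("round_robin", "alternating", "duty_cycle"),
                                  horizon_s, dwell_s = NULL,
                                  inlets = paste0("model_", 1:3),
                                  routes = c("model_1", "reference"),
                                  on_s = NULL, off_s = NULL) {
  kind <- match.arg(kind)
  check_number(horizon_s, "horizon_s", min = 0, strict_min = TRUE)

  if (kind %in% c("round_robin", "alternating")) {
    if (is.null(dwell_s)) {
      pkeye_stop(sprintf("`dwell_s` is required for a %s schedule.", kind),
                 "pkeye_schedule_error")
    }
    check_number(dwell_s, "dwell_s", min = 0, strict_min = TRUE,
                 class = "pkeye_schedule_error")
    n_win <- ceiling(horizon_s / dwell_s - 1e-9)
    starts <- (seq_len(n_win) - 1) * dwell_s
    labels <- if (kind == "round_robin") inlets else routes[1:2]
    route <- rep_len(labels, length(starts))
  } else {
    if (is.null(on_s) || is.null(off_s)) {
      pkeye_stop("`on_s` and `off_s` are required for a duty_cycle schedule.",
                 "pkeye_schedule_error")
    }
    check_number(on_s, "on_s", min = 0, strict_min = TRUE, class = "pkeye_schedule_error")
    check_number(off_s, "off_s", min = 0, class = "pkeye_schedule_error")
    cycle <- on_s + off_s
    n_cyc <- ceiling(horizon_s / cycle - 1e-9)
    cycle_starts <- (seq_len(n_cyc) - 1) * cycle
    starts <- as.vector(rbind(cycle_starts, cycle_starts + on_s))
    route <- rep_len(c(routes[1], "waste"), length(starts))
    keep <- starts < horizon_s
    starts <- starts[keep]
    route <- route[keep]
  }
  out <- tibble::tibble(time_s = starts, route = route)
  structure(out, horizon_s = horizon_s,
            class = c("switch_schedule", class(out)))
}

#' Expand a schedule into dwell windows
#'
#' @param schedule A [build_switch_schedule()] result.
#' @return Tibble with columns `route`, `start_s`, `end_s`; the windows
#'   partition `[0, horizon)`.
#' @export
schedule_windows <- function(schedule) {
  stopifnot(inherits(schedule, "switch_schedule"))
  horizon <- attr(schedule, "horizon_s")
  tibble::tibble(
    route = schedule$route,
    start_s = schedule$time_s,
    end_s = c(schedule$time_s[-1], horizon)
  )
}
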