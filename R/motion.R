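#' Segment-based eye-movement programs
#'
#' An eye-movement program is a list of segments, each a signed angular
#' displacement executed over a move duration and followed by a fixation
#' pause, plus a velocity-profile shape applied within every move. This
#' mirrors how the rotation stage is programmed: e.g. a smooth-pursuit leg of
#' +20 deg over 1.5 s with a 1 s pause, a scene saccade of +4 deg over 50 ms
#' with a 330 ms fixation, or a micro-saccade of +0.55 deg over 14 ms
#' repeating about every 1.25 s.
#'
#' The profile shape is not dictated by the stage: the net displacement per
#' segment is profile-independent, while the peak velocity is profile
#' characteristic (peak/mean = 1 rectangular, 2 triangular, 1.875 minimum
#' jerk). Triangular is the default since it reproduces the programmed
#' pursuit and saccade maxima within a few percent; minimum jerk reproduces
#' the measured pursuit peak.
#'
#' @param segments Data frame with columns `delta_deg` (signed displacement),
#'   `duration_s` (> 0 whenever `delta_deg != 0`) and `pause_s` (>= 0).
#' @param profile `"triangular"`, `"rectangular"` or `"minimum_jerk"`.
#' @param repeat_count Number of times the segment list is repeated.
#' @param sample_rate_hz Sampling rate for [build_trajectory()]; must be at
#'   least `2 / min(duration_s)` to resolve the shortest move.
#' @param name Program label.
#' @return An object of class `motion_program`.
#' @examples
#' motion_program(tibble::tibble(delta_deg = 20, duration_s = 1.5, pause_s = 1))
#' @export
motion_program <- function(segments,
                           profile = c("triangular", "rectangular", "minimum_jerk"),
                           repeat_count = 1, sample_rate_hz = 1000, name = "") {
  profile <- match.arg(profile)
  stopifnot(is.data.frame(segments))
  if (nrow(segments) > 0) {
    stopifnot(all(c("delta_deg", "duration_s", "pause_s") %in% names(segments)))
    bad <- segments$delta_deg != 0 & segments$duration_s <= 0
    if (any(bad) || any(segments$pause_s < 0) || any(segments$duration_s < 0)) {
      pkeye_stop("Each moving segment needs duration_s > 0 and pause_s >= 0.",
                 "pkeye_invalid_parameter")
    }
    moves <- segments$duration_s[segments$delta_deg != 0]
    if (length(moves) > 0 && sample_rate_hz < 2 / min(moves)) {
      pkeye_stop(sprintf(
        "sample_rate_hz = %g cannot resolve the shortest move (%g s); need >= %g Hz.",
        sample_rate_hz, min(moves), 2 / min(moves)
      ), "pkeye_resolution_error")
    }
  }
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  check_number(repeat_count, "repeat_count", min = 1)
  structure(list(name = name, segments = tibble::as_tibble(segments),
                 profile = profile, repeat_count = as.integer(repeat_count),
                 sample_rate_hz = sample_rate_hz),
            class = "motion_program")
}

#' @export
print.motion_program <- function(x, ...) {
  cat(sprintf("<motion_program> %s: %d segments x%d, %s profile, %g Hz\n",
              if (nzchar(x$name)) x$name else "(unnamed)", nrow(x$segments),
              x$repeat_count, x$profile, x$sample_rate_hz))
  invisible(x)
}

#' Shipped eye-movement presets
#'
#' Transcriptions of the three movement programs run on the physical rotation
#' stage (smooth pursuit, scene-pursuit saccades, micro-saccades), stored as
#' a JSON data file under `inst/extdata/motion_presets.json`. Two additional
#' `*_programmed` variants carry the originally programmed parameters where
#' these differ from the executed table (pursuit legs of 20 deg/1.8 s;
#' micro-saccades of 0.4 deg/20 ms); both versions are shipped unmodified
#' rather than reconciled.
#'
#' @param name Preset name; one of `"smooth_pursuit"`,
#'   `"smooth_pursuit_programmed"`, `"scene_saccades"`, `"micro_saccades"`,
#'   `"micro_saccades_programmed"`. Call with no arguments to list them.
#' @param profile,sample_rate_hz,repeat_count Passed to [motion_program()].
#' @return A [motion_program()], or a character vector of names when `name`
#'   is missing.
#' @examples
#' motion_preset()
#' motion_preset("scene_saccades")
#' @export
motion_preset <- function(name, profile = "triangular",
                          sample_rate_hz = 2000, repeat_count = 1) {
  presets <- jsonlite::fromJSON(
    system.file("extdata", "motion_presets.json", package = "pkeyesim"),
    simplifyDataFrame = TRUE
  )
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets)) {
    pkeye_stop(sprintf("Unknown motion preset '%s'. Available: %s.",
                       name, paste(names(presets), collapse = ", ")),
               "pkeye_key_error")
  }
  motion_program(tibble::as_tibble(presets[[name]]), profile = profile,
                 repeat_count = repeat_count, sample_rate_hz = sample_rate_hz,
                 name = name)
}

# velocity-profile shapes on tau in [0,1]; position in units of delta,
# velocity in units of delta/T, acceleration in units of delta/T^2
profile_shapes <- function(profile) {
  switch(profile,
    rectangular = list(
      pos = function(tau) tau,
      vel = function(tau) rep(1, length(tau)),
      acc = function(tau) rep(0, length(tau))
    ),
    triangular = list(
      pos = function(tau) ifelse(tau < 0.5, 2 * tau^2, 1 - 2 * (1 - tau)^2),
      vel = function(tau) ifelse(tau < 0.5, 4 * tau, 4 * (1 - tau)),
      acc = function(tau) ifelse(tau < 0.5, 4, -4)
    ),
    minimum_jerk = list(
      pos = function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
      vel = function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4,
      acc = function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3
    )
  )
}

#' Build a sampled trajectory from a motion program
#'
#' Expands the program into a uniformly sampled angular trajectory. Within
#' each segment the chosen velocity profile integrates exactly to the
#' commanded displacement; pauses hold the angle; the angle is continuous
#' across segment boundaries. Velocity and acceleration are the analytic
#' derivatives of the position profile, so the trapezoidal integral of the
#' sampled velocity reproduces the displacement to well under 0.1% of total
#' travel at the default rates.
#'
#' @param program A [motion_program()].
#' @return A tibble of class `eye_trajectory` with columns `time_s`,
#'   `angle_deg`, `velocity_deg_s`, `accel_deg_s2`, `segment` (0 = pause /
#'   initial rest). An empty program yields a single sample at 0 deg.
#' @examples
#' traj <- build_trajectory(motion_preset("smooth_pursuit"))
#' peak_velocity(traj)
#' @export
build_trajectory <- function(program) {
  stopifnot(inherits(program, "motion_program"))
  segs <- program$segments
  if (nrow(segs) == 0 || program$repeat_count < 1) {
    out <- tibble::tibble(time_s = 0, angle_deg = 0, velocity_deg_s = 0,
                          accel_deg_s2 = 0, segment = 0L)
    return(structure(out, class = c("eye_trajectory", class(out))))
  }
  segs <- segs[rep(seq_len(nrow(segs)), program$repeat_count), ]
  shapes <- profile_shapes(program$profile)
  dt <- 1 / program$sample_rate_hz

  # phase table: one row per move and per (positive) pause
  starts <- cumsum(c(0, utils::head(segs$duration_s + segs$pause_s, -1)))
  angle0 <- cumsum(c(0, utils::head(segs$delta_deg, -1)))
  total <- sum(segs$duration_s + segs$pause_s)
  t <- seq(0, total, by = dt)
  if (t[length(t)] < total) t <- c(t, total)

  angle <- numeric(length(t))
  vel <- numeric(length(t))
  acc <- numeric(length(t))
  seg_id <- integer(length(t))

  idx <- findInterval(t, starts, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  for (i in seq_len(nrow(segs))) {
    sel <- idx == i
    if (!any(sel)) next
    tt <- t[sel] - starts[i]
    dur <- segs$duration_s[i]
    moving <- segs$delta_deg[i] != 0 & tt < dur
    tau <- pmin(pmax(tt / max(dur, .Machine$double.eps), 0), 1)
    a0 <- angle0[i]
    d <- segs$delta_deg[i]
    angle[sel] <- ifelse(moving, a0 + d * shapes$pos(tau), a0 + d)
    vel[sel] <- ifelse(moving, d / dur * shapes$vel(tau), 0)
    acc[sel] <- ifelse(moving, d / dur^2 * shapes$acc(tau), 0)
    seg_id[sel] <- ifelse(moving, i, 0L)
  }
  # the very last sample sits at the end of the final phase
  angle[length(t)] <- sum(segs$delta_deg)
  vel[length(t)] <- 0
  acc[length(t)] <- 0

  out <- tibble::tibble(time_s = t, angle_deg = angle, velocity_deg_s = vel,
                        accel_deg_s2 = acc, segment = seg_id)
  structure(out, class = c("eye_trajectory", class(out)))
}

#' Peak angular speed of a trajectory
#'
#' @param trajectory An `eye_trajectory` from [build_trajectory()] (or any
#'   data frame with a `velocity_deg_s` column); must be non-empty.
#' @return Maximum of `|velocity|`, deg/s.
#' @export
peak_velocity <- function(trajectory) {
  stopifnot(is.data.frame(trajectory), nrow(trajectory) > 0,
            "velocity_deg_s" %in% names(trajectory))
  max(abs(trajectory$velocity_deg_s))
}

#' Kinematic summary of a trajectory
#'
#' @param trajectory An `eye_trajectory` from [build_trajectory()].
#' @return One-row tibble: net displacement, total travel, peak velocity,
#'   peak acceleration, duration.
#' @export
motion_summary <- function(trajectory) {
  stopifnot(is.data.frame(trajectory), nrow(trajectory) > 0)
  tibble::tibble(
    duration_s = max(trajectory$time_s) - min(trajectory$time_s),
    net_displacement_deg = trajectory$angle_deg[nrow(trajectory)] - trajectory$angle_deg[1],
    total_travel_deg = sum(abs(diff(trajectory$angle_deg))),
    peak_velocity_deg_s = peak_velocity(trajectory),
    peak_accel_deg_s2 = max(abs(trajectory$accel_deg_s2))
  )
}

#' Synthesize an accelerometer trace from a trajectory
#'
#' Models a single-axis tangential accelerometer mounted at `mount_radius_m`
#' from the rotation axis: `a = r * alpha` with the angular acceleration in
#' rad/s^2, resampled to the accelerometer's acquisition rate (6.4 kHz by
#' default, i.e. 6400 points per second) plus optional Gaussian sensor
#' noise. Centripetal acceleration (`r * omega^2`) is excluded by default
#' and can be added with `include_centripetal = TRUE`.
#'
#' @param trajectory An `eye_trajectory` from [build_trajectory()].
#' @param mount_radius_m Sensor mounting radius, m; > 0 (default 0.10).
#' @param sample_rate_hz Acquisition rate, Hz (default 6400).
#' @param noise_sd Gaussian noise SD, m/s^2.
#' @param seed Optional integer seed.
#' @param include_centripetal Add the radial `r * omega^2` component.
#' @return Tibble with columns `time_s`, `accel_m_s2`; `floor(span * rate)`
#'   samples on a half-open grid, so one second yields exactly 6400 samples
#'   at the default rate.
#' @export
synth_accelerometer <- function(trajectory, mount_radius_m = 0.10,
                                sample_rate_hz = 6400, noise_sd = 0,
                                seed = NULL, include_centripetal = FALSE) {
  stopifnot(is.data.frame(trajectory), nrow(trajectory) > 0)
  check_number(mount_radius_m, "mount_radius_m", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  if (!is.null(seed)) set.seed(seed)
  t0 <- min(trajectory$time_s)
  span <- max(trajectory$time_s) - t0
  n <- max(1L, floor(span * sample_rate_hz))
  t <- t0 + (seq_len(n) - 1) / sample_rate_hz
  interp <- function(y) {
    if (nrow(trajectory) == 1) rep(y, n)
    else stats::approx(trajectory$time_s, y, xout = t, rule = 2)$y
  }
  alpha <- interp(trajectory$accel_deg_s2) * pi / 180
  a <- mount_radius_m * alpha
  if (include_centripetal) {
    omega <- interp(trajectory$velocity_deg_s) * pi / 180
    a <- a + mount_radius_m * omega^2
  }
  if (noise_sd > 0) a <- a + stats::rnorm(n, 0, noise_sd)
  tibble::tibble(time_s = t, accel_m_s2 = a)
}

#' Synthesize platform temperature telemetry
#'
#' The heated platform is monitored by PT-100 probes logged at 1 Hz; under
#' vivarium-lamp heating the two probes read 35.3 +/- 0.6 degC and 34.0 +/-
#' 0.3 degC, within the 1.5 degC uniformity band. Readings are modelled as
#' Gaussian around each probe's setpoint.
#'
#' @param duration_s Trace duration, s; >= 1.
#' @param setpoints Named numeric vector of probe setpoints, degC.
#' @param noise_sd Per-probe reading SD, degC (recycled).
#' @param sample_rate_hz Sampling rate, Hz (default 1).
#' @param seed Optional integer seed.
#' @return Tibble with columns `time_s`, `probe`, `temp_c`.
#' @export
synth_temperature <- function(duration_s,
                              setpoints = c(probe_1 = 35.3, probe_2 = 34.0),
                              noise_sd = c(0.6, 0.3),
                              sample_rate_hz = 1, seed = NULL) {
  check_number(duration_s, "duration_s", min = 1)
  noise_sd <- rep_len(noise_sd, length(setpoints))
  if (any(noise_sd < 0)) pkeye_stop("`noise_sd` must be >= 0.", "pkeye_invalid_parameter")
  if (!is.null(seed)) set.seed(seed)
  n <- max(1L, floor(duration_s * sample_rate_hz))
  t <- (seq_len(n) - 1) / sample_rate_hz
  purrr::imap_dfr(as.list(setpoints), function(sp, nm) {
    i <- match(nm, names(setpoints))
    tibble::tibble(
      time_s = t, probe = nm,
      temp_c = sp + if (noise_sd[i] > 0) stats::rnorm(n, 0, noise_sd[i]) else 0
    )
  })
}
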