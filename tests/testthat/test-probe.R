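test_that("calibration inverts exactly at zero noise and rejects bad designs", {
  quiet <- probe_config(calibration_noise_sd_ug_ml = 0)
  fit <- fit_calibration(probe = quiet)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, quiet$response_factor, tolerance = 1e-9)

  # round trip across the standards range is the identity
  conc <- calibration_standards()
  back <- auc_to_concentration(quiet$response_factor * conc, fit)
  expect_equal(back$conc_ug_ml, conc, tolerance = 1e-9)
  expect_false(any(back$clipped))

  # a noisy blank below the intercept clips to zero with a flag
  blank <- auc_to_concentration(fit$intercept - 5, fit)
  expect_equal(blank$conc_ug_ml, 0)
  expect_true(blank$clipped)

  expect_error(fit_calibration(standards = c(10, 20), probe = quiet),
               class = "pkeye_fitting_error")
  expect_error(fit_calibration(standards = rep(10, 5), probe = quiet),
               class = "pkeye_fitting_error")
  bad <- fit
  bad$slope <- -1
  expect_error(auc_to_concentration(100, bad), class = "pkeye_calibration_error")
})

test_that("default-noise calibration reaches instrument-grade linearity", {
  fit <- fit_calibration(seed = 11)
  expect_gte(fit$r_squared, 0.99)
  expect_lt(fit$r_squared, 1)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("switch schedules tile the horizon exactly", {
  rr <- build_switch_schedule("round_robin", horizon_s = 3600, dwell_s = 600,
                              inlets = c("model_1", "model_2", "model_3"))
  w <- schedule_windows(rr)
  expect_equal(nrow(w), 6)
  expect_equal(w$route, rep(c("model_1", "model_2", "model_3"), 2))

  duty <- build_switch_schedule("duty_cycle", horizon_s = 25 * 3600,
                                on_s = 20 * 60, off_s = 280 * 60)
  wd <- schedule_windows(duty)
  waste_gaps <- wd$end_s[wd$route == "waste"] - wd$start_s[wd$route == "waste"]
  expect_true(all(utils::head(waste_gaps, -1) == 280 * 60))

  # single-inlet round robin is one continuous window
  single <- build_switch_schedule("round_robin", horizon_s = 3600,
                                  dwell_s = 3600, inlets = "model_1")
  expect_equal(nrow(schedule_windows(single)), 1)

  # partition property on a 1 s grid for all three kinds
  alt <- build_switch_schedule("alternating", horizon_s = 8 * 3600, dwell_s = 2 * 3600)
  for (sch in list(rr, duty, alt)) {
    win <- schedule_windows(sch)
    expect_equal(sum(win$end_s - win$start_s), attr(sch, "horizon_s"))
    grid <- seq(0, attr(sch, "horizon_s") - 1)
    hits <- sapply(grid, function(g) sum(g >= win$start_s & g < win$end_s))
    expect_true(all(hits == 1))
  }

  expect_error(build_switch_schedule("round_robin", horizon_s = 100, dwell_s = 0),
               class = "pkeye_schedule_error")
  expect_error(build_switch_schedule("duty_cycle", horizon_s = 100),
               class = "pkeye_schedule_error")
})

test_that("routing samples only probe windows and tracks the routed flow", {
  horizon <- 3600
  t <- seq(0, horizon, by = 60)
  inlets <- dplyr::bind_rows(
    tibble::tibble(route = "model_1", time_s = t, conc_ug_ml = 10, flow_uL_min = 1.5),
    tibble::tibble(route = "model_2", time_s = t, conc_ug_ml = 20, flow_uL_min = 2.0),
    tibble::tibble(route = "model_3", time_s = t, conc_ug_ml = 30, flow_uL_min = 2.5)
  )
  rr <- build_switch_schedule("round_robin", horizon_s = horizon, dwell_s = 600,
                              inlets = paste0("model_", 1:3))
  run <- route_and_sample(inlets, rr, probe_config(noise_sd_ug_ml = 0))

  # selector outflow steps through the three inlet flows in order
  by_win <- run$outflow |>
    dplyr::mutate(win = findInterval(time_s, rr$time_s)) |>
    dplyr::group_by(win) |>
    dplyr::summarise(f = unique(flow_uL_min), .groups = "drop")
  expect_equal(by_win$f, rep(c(1.5, 2.0, 2.5), 2))
  expect_equal(unique(run$probe_trace$conc_ug_ml[run$probe_trace$route == "model_2"]), 20)

  # an always-waste schedule produces no probe readings
  waste <- build_switch_schedule("duty_cycle", horizon_s = horizon,
                                 on_s = 1e-6, off_s = horizon)
  waste$route[1] <- "waste"  # both windows to waste
  run2 <- route_and_sample(inlets, waste, probe_config())
  expect_equal(nrow(run2$probe_trace), 0)

  # unknown scheduled route fails fast
  bad <- build_switch_schedule("round_robin", horizon_s = horizon, dwell_s = 600,
                               inlets = c("model_1", "model_9", "model_3"))
  expect_error(route_and_sample(inlets, bad, probe_config()),
               class = "pkeye_routing_error")

  # horizon longer than the traces fails fast
  long <- build_switch_schedule("round_robin", horizon_s = 2 * horizon,
                                dwell_s = 600, inlets = "model_1")
  expect_error(route_and_sample(inlets, long, probe_config()),
               class = "pkeye_routing_error")
})

test_that("gapped duty-cycle sampling reconstructs the clearance profile", {
  # known monoexponential, 20 days, t1/2 = 8 days
  t <- seq(0, 20 * 86400, by = 60)
  inlet <- tibble::tibble(route = "model_1", time_s = t,
                          conc_ug_ml = 100 * 2^(-t / (8 * 86400)), flow_uL_min = 2)
  duty <- build_switch_schedule("duty_cycle", horizon_s = 20 * 86400,
                                on_s = 20 * 60, off_s = 280 * 60)
  run <- route_and_sample(inlet, duty, probe_config(), seed = 3)

  # sample-run gaps equal the waste interval
  rec <- reconstruct_profile(run$probe_trace, read_interval_s = 60)
  expect_equal(nrow(rec), sum(schedule_windows(duty)$route != "waste"))
  gaps <- attr(rec, "gaps_s")
  expect_true(all(abs(gaps - 280 * 60) <= 60))

  # window means recover the generating half-life within 5%
  hl <- estimate_half_life(rec, t_mid_s, mean_conc_ug_ml)
  expect_lt(abs(hl$half_life_days / 8 - 1), 0.05)

  # a continuous trace is a single window
  one <- reconstruct_profile(tibble::tibble(time_s = seq(0, 600, 60),
                                            conc_ug_ml = 5), 60)
  expect_equal(nrow(one), 1)
  expect_error(reconstruct_profile(tibble::tibble(time_s = numeric(),
                                                  conc_ug_ml = numeric())),
               class = "pkeye_empty_trace_error")
})

test_that("probe config enforces its acquisition constraints", {
  expect_error(probe_config(read_interval_s = 0.1, integration_window_ms = 250),
               class = "pkeye_invalid_parameter")
  expect_error(probe_config(response_factor = 0), class = "pkeye_invalid_parameter")
  expect_error(probe_config(noise_sd_ug_ml = -1), class = "pkeye_invalid_parameter")
})
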