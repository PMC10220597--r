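test_that("a zero dose clears nothing and a flat trace has no half-life", {
  sim <- simulate_clearance(eye_model_config("first_generation"),
                            drug_spec(dose_mass_ug = 0),
                            duration_s = 3600, step_s = 60)
  expect_true(all(sim$traces$conc_posterior_ug_ml == 0))
  expect_true(all(sim$traces$conc_anterior_ug_ml == 0))
  expect_null(sim$half_life)

  flat <- tibble::tibble(time_s = seq(0, 9) * 3600, conc = rep(5, 10))
  expect_error(estimate_half_life(flat, time_s, conc),
               class = "pkeye_undefined_half_life_error")
})

test_that("single-compartment limit matches t1/2 = ln2 V/Q", {
  # anterior injection, no membrane exchange: one well-mixed compartment of
  # 1 mL flushed at 2 uL/min -> t1/2 = ln2 * 1000/2 = 346.57 min
  m <- eye_model_config("intracameral", anterior_volume_ml = 1,
                        aqueous_inflow_ulmin = 2,
                        hyaloid_transfer_ulmin = 0, hyaloid_sieving = 0)
  d <- drug_spec(dose_mass_ug = 500, injection_volume_ul = 100,
                 injection_site = "anterior")
  sim <- simulate_clearance(m, d, duration_s = 2 * 346.57 * 60, step_s = 60)
  hl <- estimate_half_life(sim$traces, time_s, conc_anterior_ug_ml)
  expect_equal(hl$half_life_days * 1440, log(2) * 1000 / 2, tolerance = 1e-4)
})

test_that("the adaptive solution matches a fine-step explicit integrator", {
  m <- eye_model_config("first_generation")
  d <- drug_spec()
  sim <- simulate_clearance(m, d, duration_s = 86400, step_s = 600)
  orc <- euler_clearance(m, d, duration_s = 86400, out_step_s = 600, dt_s = 6)
  scale <- max(orc$conc_posterior_ug_ml)
  expect_lt(max(abs(sim$traces$conc_posterior_ug_ml - orc$conc_posterior_ug_ml)) / scale, 1e-3)
  scale_a <- max(orc$conc_anterior_ug_ml)
  expect_lt(max(abs(sim$traces$conc_anterior_ug_ml - orc$conc_anterior_ug_ml)) / scale_a, 1e-3)
})

test_that("mass is conserved and deposited dose equals residual plus cleared", {
  for (proto in c("first_generation", "ciliary_inflow", "rcs")) {
    m <- eye_model_config(proto)
    sim <- simulate_clearance(m, drug_spec(), duration_s = 5 * 86400, step_s = 600)
    expect_lt(sim$mass_balance_rel_err, 1e-3)
    last <- dplyr::slice_tail(sim$traces, n = 1)
    resident <- last$conc_posterior_ug_ml * m$posterior_volume_ml +
      last$conc_anterior_ug_ml * m$anterior_volume_ml
    expect_equal(resident + last$cleared_anterior_ug + last$cleared_posterior_ug,
                 500, tolerance = 0.001 * 500)
  }
})

test_that("step validator and injection-volume guard reject bad setups", {
  m <- eye_model_config("first_generation")
  expect_error(simulate_clearance(m, drug_spec(), duration_s = 86400, step_s = 3600),
               class = "pkeye_stability_error")
  expect_error(
    simulate_clearance(m, drug_spec(injection_volume_ul = 5000),
                       duration_s = 3600, step_s = 60),
    class = "pkeye_configuration_error"
  )
  expect_error(eye_model_config("first_generation", rcs_transfer_ulmin = 1),
               class = "pkeye_configuration_error")
})

test_that("half-life estimation inverts a known exponential and handles noise", {
  t <- seq(0, 40 * 86400, by = 6 * 3600)
  tr <- tibble::tibble(time_s = t, conc = 100 * 2^(-t / (8.1 * 86400)))
  hl <- estimate_half_life(tr, time_s, conc)
  expect_equal(hl$half_life_days, 8.1, tolerance = 1e-6)
  expect_equal(hl$r_squared, 1, tolerance = 1e-9)
  expect_s3_class(glance(hl), "tbl_df")

  # seeded 5% multiplicative noise, n = 200, within 5% of 10.1 days
  set.seed(1)
  t2 <- seq(0, 30 * 86400, length.out = 200)
  tr2 <- tibble::tibble(time_s = t2,
                        conc = 50 * 2^(-t2 / (10.1 * 86400)) *
                          exp(stats::rnorm(200, 0, 0.05)))
  hl2 <- estimate_half_life(tr2, time_s, conc)
  expect_lt(abs(hl2$half_life_days / 10.1 - 1), 0.05)

  expect_error(estimate_half_life(tr[1:3, ], time_s, conc),
               class = "pkeye_window_error")
  neg <- tibble::tibble(time_s = t, conc = c(-1, tr$conc[-1]))
  expect_error(estimate_half_life(neg, time_s, conc), class = "pkeye_window_error")
})

test_that("faster aqueous turnover never lengthens the terminal half-life", {
  hl <- sapply(c(1, 1.5, 2, 2.5, 3), function(q) {
    m <- eye_model_config("first_generation", aqueous_inflow_ulmin = q)
    simulate_clearance(m, drug_spec(), duration_s = 15 * 86400,
                       step_s = 500)$half_life$half_life_days
  })
  expect_true(all(diff(hl) <= 0))
})

test_that("large membrane transfer collapses to the whole-volume closed form", {
  m <- eye_model_config("first_generation", hyaloid_transfer_ulmin = 100 * 2,
                        hyaloid_sieving = 1)
  sim <- simulate_clearance(m, drug_spec(), duration_s = 6 * 86400, step_s = 8)
  closed <- log(2) * (4000 + 300) / 2 / 1440  # days
  expect_lt(abs(sim$half_life$half_life_days / closed - 1), 0.01)
})

test_that("hyaloid transfer is recoverable from the outlet trace", {
  m <- eye_model_config("first_generation")
  d <- drug_spec()
  sim <- simulate_clearance(m, d, duration_s = 10 * 86400, step_s = 600)
  set.seed(5)
  obs <- sim$traces$conc_anterior_ug_ml * exp(stats::rnorm(nrow(sim$traces), 0, 0.05))
  sse <- function(pa) {
    mm <- eye_model_config("first_generation", hyaloid_transfer_ulmin = pa)
    pred <- simulate_clearance(mm, d, duration_s = 10 * 86400, step_s = 600)
    sum((pred$traces$conc_anterior_ug_ml - obs)^2)
  }
  pa_hat <- stats::optimize(sse, c(0.05, 0.5), tol = 1e-4)$minimum
  expect_lt(abs(pa_hat / 0.15 - 1), 0.10)
})

test_that("the rcs prototype splits elimination between both outlets", {
  m <- eye_model_config("rcs", rcs_transfer_ulmin = 0.1)
  sim <- simulate_clearance(m, drug_spec(), duration_s = 10 * 86400, step_s = 600)
  fr <- split_elimination(sim)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-3)
  expect_true(all(fr$fraction >= 0))

  # fractions agree with the independent explicit integrator
  orc <- euler_clearance(m, drug_spec(), duration_s = 10 * 86400,
                         out_step_s = 600, dt_s = 6)
  last <- dplyr::slice_tail(orc, n = 1)
  expect_equal(fr$fraction[fr$route == "anterior"], last$cleared_anterior_ug / 500,
               tolerance = 1e-3)
  expect_equal(fr$fraction[fr$route == "posterior"], last$cleared_posterior_ug / 500,
               tolerance = 1e-3)

  # no back membrane transfer -> nothing leaves by the posterior route
  m0 <- eye_model_config("rcs", rcs_transfer_ulmin = 0)
  sim0 <- simulate_clearance(m0, drug_spec(), duration_s = 86400, step_s = 600)
  fr0 <- split_elimination(sim0)
  expect_equal(fr0$fraction[fr0$route == "posterior"], 0)

  expect_error(split_elimination(simulate_clearance(
    eye_model_config("first_generation"), drug_spec(),
    duration_s = 3600, step_s = 60
  )), class = "pkeye_mode_error")
})

test_that("clearance tidiers summarise the run", {
  sim <- simulate_clearance(eye_model_config("first_generation"), drug_spec(),
                            duration_s = 5 * 86400, step_s = 600)
  g <- glance(sim)
  expect_equal(g$prototype, "first_generation")
  expect_true(g$half_life_days > 5 && g$half_life_days < 15)
  expect_true(all(c("time_s", "series", "value") %in% names(tidy(sim))))
})
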