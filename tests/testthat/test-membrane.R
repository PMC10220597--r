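test_that("pore pressure drop reproduces the channel-plus-orifice arithmetic", {
  # term-by-term oracle: evaluate the Poiseuille and Sampson contributions
  # separately and sum
  mu <- 1.0e-3
  T_ <- 50e-6
  R <- 5e-6
  Q <- 1.0e-13
  poiseuille <- 8 * mu * T_ * Q / (pi * R^4)
  sampson <- 3 * mu * Q / R^3
  mem <- membrane_spec(NA, exposed_diameter_m = 20e-3, pore_radius_m = R,
                       thickness_m = T_)
  got <- pore_pressure_drop(fluid_spec("PBS", mu), mem, Q)
  expect_equal(got, poiseuille + sampson, tolerance = 1e-12)
  expect_equal(got, 22.77183, tolerance = 1e-6)  # frozen regression value

  # zero flow and zero thickness degenerate cases
  expect_identical(pore_pressure_drop(test_fluid(), mem, 0), 0)
  mem0 <- membrane_spec(NA, exposed_diameter_m = 20e-3, pore_radius_m = R,
                        thickness_m = 0)
  expect_equal(pore_pressure_drop(fluid_spec("PBS", mu), mem0, Q), sampson,
               tolerance = 1e-14)
})

test_that("specs reject non-physical parameters", {
  expect_error(fluid_spec("x", 0), class = "pkeye_invalid_parameter")
  expect_error(membrane_spec(300, exposed_diameter_m = 20e-3, pore_radius_m = -1e-9),
               class = "pkeye_invalid_parameter")
  expect_error(membrane_spec(300, exposed_diameter_m = 1e-9),
               class = "pkeye_invalid_parameter")  # pore >= exposed radius
  expect_error(pore_pressure_drop(test_fluid(), test_membrane(), -1),
               class = "pkeye_invalid_parameter")
  # zero pore count in the exposed area
  tiny <- membrane_spec(NA, exposed_diameter_m = 1e-6, pore_radius_m = 1e-9,
                        pore_density_m2 = 1)
  expect_error(membrane_flow(test_fluid(), tiny, 10), class = "pkeye_configuration_error")
})

test_that("the model is linear in flow and monotone in geometry", {
  set.seed(11)
  fl <- fluid_spec("x", 0.05)
  mem <- test_membrane(50)
  q <- 1e-15
  for (a in c(0, 0.5, 2, 17.3)) {
    expect_equal(pore_pressure_drop(fl, mem, a * q),
                 a * pore_pressure_drop(fl, mem, q), tolerance = 1e-12)
  }
  # larger pores, larger exposed area -> more flow at fixed pressure
  flows_r <- sapply(c(2e-9, 4e-9, 12e-9), function(r)
    membrane_flow(fl, membrane_spec(NA, 20e-3, pore_radius_m = r), 100))
  expect_true(all(diff(flows_r) > 0))
  flows_d <- sapply(c(5e-3, 15e-3, 20e-3), function(d)
    membrane_flow(fl, membrane_spec(300, exposed_diameter_m = d), 100))
  expect_true(all(diff(flows_d) > 0))
})

test_that("forward and inverse models round-trip over random parameter draws", {
  set.seed(101)
  n <- 1000
  worst <- 0
  for (i in seq_len(n)) {
    fl <- fluid_spec("x", stats::runif(1, 1e-3, 0.8))
    mem <- membrane_spec(NA,
      exposed_diameter_m = stats::runif(1, 5e-3, 20e-3),
      pore_radius_m = stats::runif(1, 1e-9, 1e-7),
      thickness_m = stats::runif(1, 0, 1e-4),
      pore_density_m2 = 10^stats::runif(1, 10, 13)
    )
    q_pore <- 10^stats::runif(1, -22, -15)
    dp <- pore_pressure_drop(fl, mem, q_pore)
    q_back <- membrane_flow(fl, mem, dp) / n_pores(mem)
    worst <- max(worst, abs(q_back / q_pore - 1))
  }
  expect_lt(worst, 1e-9)
})

test_that("pressure/flow unit conversions invert exactly", {
  expect_equal(pa_to_mmHg(mmHg_to_pa(361)), 361, tolerance = 1e-14)
  expect_equal(m3s_to_ulmin(ulmin_to_m3s(2)), 2, tolerance = 1e-14)
  expect_equal(mmHg_to_pa(1), 133.322)
})

test_that("effective pore radius is recovered from self-generated data", {
  fl <- test_fluid()
  r_true <- 12e-9
  mem <- membrane_spec(NA, 20e-3, pore_radius_m = r_true)
  # noiseless single point
  q <- membrane_flow_ulmin(fl, mem, 100)
  fit <- fit_pore_radius(tibble::tibble(pressure_mmHg = 100, flow_uL_min = q),
                         fl, exposed_diameter_m = 20e-3)
  expect_lt(abs(fit$pore_radius_m / r_true - 1), 1e-3)

  # two points with 5% multiplicative noise, fixed seed
  set.seed(7)
  dp <- c(50, 200)
  qs <- membrane_flow_ulmin(fl, mem, dp) * exp(stats::rnorm(2, 0, 0.05))
  fit2 <- fit_pore_radius(tibble::tibble(pressure_mmHg = dp, flow_uL_min = qs),
                          fl, exposed_diameter_m = 20e-3)
  expect_lt(abs(fit2$pore_radius_m / r_true - 1), 0.10)
  expect_s3_class(glance(fit2), "tbl_df")
  expect_equal(nrow(tidy(fit2)), 2)

  expect_error(
    fit_pore_radius(tibble::tibble(pressure_mmHg = c(10, 20), flow_uL_min = c(0, 0)),
                    fl, exposed_diameter_m = 20e-3),
    class = "pkeye_fitting_error"
  )
})

test_that("stepped sweeps hold analytic flow per plateau with no hysteresis", {
  fl <- test_fluid()
  mem <- test_membrane(300)
  # zero noise, one step
  tr <- stepped_pressure_sweep(fl, mem, 10, hold_duration_s = 5, sample_rate_hz = 2)
  expect_true(all(tr$flow_uL_min == membrane_flow_ulmin(fl, mem, 10)))
  expect_equal(nrow(tr), 10)

  # seeded up/down staircase: per-level means match analytic values and the
  # descending branch mirrors the ascending one within 3 sigma / sqrt(n)
  up <- seq(20, 200, length.out = 10)
  steps <- c(up, rev(up))
  sigma <- 0.01
  n_per <- 50
  tr2 <- stepped_pressure_sweep(fl, mem, steps, hold_duration_s = n_per,
                                sample_rate_hz = 1, noise_sd_ulmin = sigma,
                                seed = 42)
  means <- tr2 |>
    dplyr::group_by(step) |>
    dplyr::summarise(p = pressure_mmHg[1], m = mean(flow_uL_min), .groups = "drop")
  bound <- 3 * sigma / sqrt(n_per)
  expect_true(all(abs(means$m - membrane_flow_ulmin(fl, mem, means$p)) < bound))
  asc <- means$m[1:10]
  desc <- rev(means$m[11:20])
  expect_true(all(abs(asc - desc) < 2 * bound))

  expect_error(stepped_pressure_sweep(fl, mem, 10, 5, noise_sd_ulmin = -1),
               class = "pkeye_invalid_parameter")
})

test_that("sweeping past a membrane's pressure ceiling raises a rupture error", {
  mem <- membrane_spec(300, exposed_diameter_m = 20e-3, pressure_ceiling_mmHg = 100)
  expect_error(stepped_pressure_sweep(test_fluid(), mem, c(50, 150), 10),
               class = "pkeye_rupture_error")
  # below the ceiling the sweep is unaffected
  expect_silent(stepped_pressure_sweep(test_fluid(), mem, c(50, 90), 1))
})

test_that("MWCO lookup provides only the published cut-offs", {
  expect_equal(mwco_pore_radius(12.5), 2e-9)
  expect_equal(mwco_pore_radius(50), 4e-9)
  expect_equal(mwco_pore_radius(300), 12e-9)
  expect_error(mwco_pore_radius(100), class = "pkeye_invalid_parameter")
})
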