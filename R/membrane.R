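#' Fluid specification
#'
#' Carrier for the fluid properties entering the membrane pressure-drop
#' model. The only property the model needs is the dynamic (shear) viscosity.
#' PBS at lab temperature is close to water (~1e-3 Pa s); simulated vitreous
#' fluid (3.0 mg/mL hyaluronate) is ~0.6-0.8 Pa s.
#'
#' @param name Label for the fluid.
#' @param viscosity_pa_s Dynamic viscosity in Pa s; must be > 0.
#' @return An object of class `fluid_spec`.
#' @examples
#' pbs <- fluid_spec("PBS", 1e-3)
#' svf <- fluid_spec("SVF", 0.7)
#' @export
fluid_spec <- function(name = "PBS", viscosity_pa_s = 1e-3) {
  check_number(viscosity_pa_s, "viscosity_pa_s", min = 0, strict_min = TRUE)
  structure(list(name = as.character(name), viscosity_pa_s = viscosity_pa_s),
            class = "fluid_spec")
}

#' @export
print.fluid_spec <- function(x, ...) {
  cat(sprintf("<fluid_spec> %s: viscosity %g Pa s\n", x$name, x$viscosity_pa_s))
  invisible(x)
}

#' Default effective pore radius for a dialysis-membrane cut-off
#'
#' The molecular-weight cut-off (MWCO) of a dialysis membrane is a proxy for
#' pore size, but no absolute pore radii are published for the Visking
#' membranes characterised on the pursing rig. This lookup ships calibration
#' seeds only -- 12-14 kDa -> 2 nm, 50 kDa -> 4 nm, 300 kDa -> 12 nm -- chosen
#' so that relative orderings (higher MWCO, larger pore, lower pressure drop)
#' hold; absolute flow predictions require fitting, see
#' [fit_pore_radius()]. Override via the `pore_radius_m` argument of
#' [membrane_spec()] whenever a measured value is available.
#'
#' @param mwco_kda MWCO in kDa; accepted keys are 12-14 (any value in that
#'   interval), 50 and 300.
#' @return Pore radius in metres.
#' @examples
#' mwco_pore_radius(50)
#' @export
mwco_pore_radius <- function(mwco_kda) {
  check_number(mwco_kda, "mwco_kda", min = 0, strict_min = TRUE)
  if (mwco_kda >= 12 && mwco_kda <= 14) return(2e-9)
  if (mwco_kda == 50) return(4e-9)
  if (mwco_kda == 300) return(12e-9)
  pkeye_stop(sprintf(
    "No default pore radius for MWCO %g kDa; supply `pore_radius_m` explicitly.",
    mwco_kda
  ), "pkeye_invalid_parameter")
}

#' Membrane specification
#'
#' Geometry of a porous membrane clamped over a circular flow area, as on the
#' two-part pursing rig: a single-pore radius, membrane thickness, the
#' exposed (clamped) diameter, and an areal pore density. Thickness and pore
#' density are not published for the characterised membranes; the defaults
#' (30 um, 1e12 pores/m^2) are calibration seeds and every fitting routine
#' exposes them as arguments.
#'
#' @param mwco_kda Molecular-weight cut-off in kDa (metadata; also selects
#'   the default pore radius via [mwco_pore_radius()]).
#' @param exposed_diameter_m Diameter of the clamped circular flow area, m.
#'   The rig used 5.0, 15.0 and 20.0 mm.
#' @param pore_radius_m Single-pore radius, m; must be > 0 and smaller than
#'   the exposed radius.
#' @param thickness_m Membrane thickness, m; >= 0 (0 reduces the model to the
#'   orifice term alone).
#' @param pore_density_m2 Pores per unit area, 1/m^2; > 0.
#' @param pressure_ceiling_mmHg Optional rupture ceiling: sweeping above this
#'   pressure raises a rupture error (membranes tear at high pressure).
#'   `NULL` (default) disables rupture.
#' @return An object of class `membrane_spec`.
#' @examples
#' membrane_spec(300, exposed_diameter_m = 20e-3)
#' @export
membrane_spec <- function(mwco_kda = 300,
                          exposed_diameter_m = 20e-3,
                          pore_radius_m = mwco_pore_radius(mwco_kda),
                          thickness_m = 30e-6,
                          pore_density_m2 = 1e12,
                          pressure_ceiling_mmHg = NULL) {
  check_number(pore_radius_m, "pore_radius_m", min = 0, strict_min = TRUE)
  check_number(thickness_m, "thickness_m", min = 0)
  check_number(exposed_diameter_m, "exposed_diameter_m", min = 0, strict_min = TRUE)
  check_number(pore_density_m2, "pore_density_m2", min = 0, strict_min = TRUE)
  if (pore_radius_m >= exposed_diameter_m / 2) {
    pkeye_stop("`pore_radius_m` must be smaller than the exposed radius.",
               "pkeye_invalid_parameter")
  }
  if (!is.null(pressure_ceiling_mmHg)) {
    check_number(pressure_ceiling_mmHg, "pressure_ceiling_mmHg",
                 min = 0, strict_min = TRUE)
  }
  structure(list(
    mwco_kda = mwco_kda,
    pore_radius_m = pore_radius_m,
    thickness_m = thickness_m,
    exposed_diameter_m = exposed_diameter_m,
    pore_density_m2 = pore_density_m2,
    pressure_ceiling_mmHg = pressure_ceiling_mmHg
  ), class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf(
    "<membrane_spec> MWCO %s kDa: pore radius %g nm, thickness %g um, exposed %g mm, %g pores/m^2\n",
    format(x$mwco_kda), x$pore_radius_m * 1e9, x$thickness_m * 1e6,
    x$exposed_diameter_m * 1e3, x$pore_density_m2
  ))
  invisible(x)
}

# Hydraulic resistance of one pore, Pa per (m^3/s): channel (Poiseuille)
# term 8*mu*T/(pi*R^4) plus orifice (Sampson) term 3*mu/R^3.
pore_resistance <- function(fluid, membrane) {
  mu <- fluid$viscosity_pa_s
  R <- membrane$pore_radius_m
  T_ <- membrane$thickness_m
  8 * mu * T_ / (pi * R^4) + 3 * mu / R^3
}

#' Number of pores in the exposed membrane area
#'
#' @param membrane A [membrane_spec()].
#' @return Integer-valued pore count, `round(density * pi * (d/2)^2)`.
#' @export
n_pores <- function(membrane) {
  n <- round(membrane$pore_density_m2 * pi * (membrane$exposed_diameter_m / 2)^2)
  if (n < 1) {
    pkeye_stop("Membrane has zero pores in the exposed area; increase pore density or area.",
               "pkeye_configuration_error")
  }
  n
}

#' Pressure drop across a single membrane pore
#'
#' Forward model for flow through a short cylindrical pore: the pressure drop
#' is the sum of a Poiseuille channel term and a Sampson orifice term,
#' `dp = 8*mu*T*Q/(pi*R^4) + 3*mu*Q/R^3`, linear in the pore flow `Q`. With
#' zero thickness only the orifice term remains.
#'
#' @param fluid A [fluid_spec()].
#' @param membrane A [membrane_spec()].
#' @param pore_flow_m3s Volumetric flow through one pore, m^3/s; >= 0.
#'   Vectorised.
#' @return Pressure drop in Pa.
#' @examples
#' m <- membrane_spec(300, exposed_diameter_m = 20e-3)
#' pore_pressure_drop(fluid_spec(), m, 1e-18)
#' @export
pore_pressure_drop <- function(fluid, membrane, pore_flow_m3s) {
  stopifnot(inherits(fluid, "fluid_spec"), inherits(membrane, "membrane_spec"))
  if (any(!is.finite(pore_flow_m3s)) || any(pore_flow_m3s < 0)) {
    pkeye_stop("`pore_flow_m3s` must be finite and >= 0.", "pkeye_invalid_parameter")
  }
  pore_resistance(fluid, membrane) * pore_flow_m3s
}

#' Total flow through a membrane at a given pressure drop
#'
#' Analytic inversion of [pore_pressure_drop()] (the model is linear in
#' flow), scaled by the number of pores in the exposed area:
#' `Q_total = n_pores * dp / (8*mu*T/(pi*R^4) + 3*mu/R^3)`.
#'
#' @inheritParams pore_pressure_drop
#' @param pressure_drop_pa Pressure drop in Pa; >= 0. Vectorised.
#' @return Total volumetric flow, m^3/s.
#' @seealso [membrane_flow_ulmin()] for the mmHg / uL/min interface.
#' @export
membrane_flow <- function(fluid, membrane, pressure_drop_pa) {
  stopifnot(inherits(fluid, "fluid_spec"), inherits(membrane, "membrane_spec"))
  if (any(!is.finite(pressure_drop_pa)) || any(pressure_drop_pa < 0)) {
    pkeye_stop("`pressure_drop_pa` must be finite and >= 0.", "pkeye_invalid_parameter")
  }
  n_pores(membrane) * pressure_drop_pa / pore_resistance(fluid, membrane)
}

#' @rdname membrane_flow
#' @param pressure_drop_mmHg Pressure drop in mmHg; >= 0.
#' @return `membrane_flow_ulmin()`: total flow in uL/min.
#' @export
membrane_flow_ulmin <- function(fluid, membrane, pressure_drop_mmHg) {
  m3s_to_ulmin(membrane_flow(fluid, membrane, mmHg_to_pa(pressure_drop_mmHg)))
}

#' Fit an effective pore radius to pressure-flow data
#'
#' Calibrates the single free microstructural parameter of the membrane
#' model against measured (pressure, flow) pairs, holding thickness and pore
#' density fixed. The estimate minimises the summed squared relative flow
#' error `sum((Q_pred/Q_obs - 1)^2)`; since predicted flow is strictly
#' monotone in the pore radius the objective is unimodal and a bracketed
#' golden-section search over log-radius converges reliably.
#'
#' @param points Data frame with columns `pressure_mmHg` and `flow_uL_min`
#'   (e.g. a slice of [fixture_registry()]'s pursing tables). At least one
#'   point must have positive flow.
#' @param fluid A [fluid_spec()].
#' @param exposed_diameter_m,thickness_m,pore_density_m2 Assumed membrane
#'   geometry (see [membrane_spec()] for the calibration-seed defaults).
#' @param interval Search bracket for the radius, m.
#' @return An object of class `pore_radius_fit` with elements
#'   `pore_radius_m`, `residuals` (tibble of observed vs predicted flow) and
#'   `objective`. Has [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' pts <- tibble::tibble(pressure_mmHg = c(100, 200), flow_uL_min = c(1, 2))
#' fit <- fit_pore_radius(pts, fluid_spec(), exposed_diameter_m = 20e-3)
#' glance(fit)
#' @export
fit_pore_radius <- function(points, fluid,
                            exposed_diameter_m,
                            thickness_m = 30e-6,
                            pore_density_m2 = 1e12,
                            interval = c(1e-10, 1e-6)) {
  stopifnot(is.data.frame(points),
            all(c("pressure_mmHg", "flow_uL_min") %in% names(points)))
  pts <- dplyr::filter(points, .data$flow_uL_min > 0)
  if (nrow(pts) < 1) {
    pkeye_stop("All fixture flows are zero; the pore radius is unidentifiable.",
               "pkeye_fitting_error")
  }
  obs_q <- pts$flow_uL_min
  dp <- pts$pressure_mmHg

  predict_q <- function(radius_m) {
    mem <- membrane_spec(
      mwco_kda = NA_real_, exposed_diameter_m = exposed_diameter_m,
      pore_radius_m = radius_m, thickness_m = thickness_m,
      pore_density_m2 = pore_density_m2
    )
    membrane_flow_ulmin(fluid, mem, dp)
  }
  objective <- function(log_r) {
    sum((predict_q(exp(log_r)) / obs_q - 1)^2)
  }
  opt <- stats::optimize(objective, interval = log(interval), tol = 1e-12)
  r_hat <- exp(opt$minimum)
  pred <- predict_q(r_hat)

  structure(list(
    pore_radius_m = r_hat,
    objective = opt$objective,
    residuals = tibble::tibble(
      pressure_mmHg = dp,
      flow_obs_uL_min = obs_q,
      flow_pred_uL_min = pred,
      rel_error = pred / obs_q - 1
    ),
    assumed = list(thickness_m = thickness_m, pore_density_m2 = pore_density_m2,
                   exposed_diameter_m = exposed_diameter_m)
  ), class = "pore_radius_fit")
}

#' @export
print.pore_radius_fit <- function(x, ...) {
  cat(sprintf("<pore_radius_fit> effective pore radius %.4g nm (%d points, rel RMSE %.3g)\n",
              x$pore_radius_m * 1e9, nrow(x$residuals),
              sqrt(mean(x$residuals$rel_error^2))))
  invisible(x)
}

#' Simulate a stepped pressure sweep across a membrane
#'
#' Reproduces the automated pursing protocol: pressure is held at each step
#' for `hold_duration_s` while flow is recorded, typically stepping up and
#' then back down to check for hysteresis (the model itself has none, so
#' ascending and descending holds at the same pressure have equal mean flow
#' up to sensor noise).
#'
#' @inheritParams pore_pressure_drop
#' @param pressure_steps_mmHg Ordered vector of pressure plateaus, mmHg.
#'   Pass `c(up, rev(up))` for an up-then-down staircase.
#' @param hold_duration_s Dwell at each plateau, s; > 0.
#' @param sample_rate_hz Recording rate, Hz (default 1, the platform's
#'   standard logging rate).
#' @param noise_sd_ulmin Flow-sensor noise standard deviation, uL/min; >= 0.
#' @param seed Optional integer seed for the noise stream.
#' @return Tibble with columns `time_s`, `step`, `pressure_mmHg`,
#'   `flow_uL_min`.
#' @examples
#' m <- membrane_spec(300, exposed_diameter_m = 20e-3)
#' sweep <- stepped_pressure_sweep(fluid_spec(), m, c(5, 10), 10)
#' @export
stepped_pressure_sweep <- function(fluid, membrane, pressure_steps_mmHg,
                                   hold_duration_s, sample_rate_hz = 1,
                                   noise_sd_ulmin = 0, seed = NULL) {
  stopifnot(inherits(fluid, "fluid_spec"), inherits(membrane, "membrane_spec"))
  if (length(pressure_steps_mmHg) < 1) {
    pkeye_stop("`pressure_steps_mmHg` must be non-empty.", "pkeye_invalid_parameter")
  }
  check_number(hold_duration_s, "hold_duration_s", min = 0, strict_min = TRUE)
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  check_number(noise_sd_ulmin, "noise_sd_ulmin", min = 0)
  ceiling <- membrane$pressure_ceiling_mmHg
  if (!is.null(ceiling) && any(pressure_steps_mmHg > ceiling)) {
    pkeye_stop(sprintf(
      "Membrane rupture: step pressure %g mmHg exceeds the %g mmHg ceiling.",
      max(pressure_steps_mmHg), ceiling
    ), "pkeye_rupture_error")
  }
  if (!is.null(seed)) set.seed(seed)

  n_per <- max(1L, floor(hold_duration_s * sample_rate_hz))
  dt <- 1 / sample_rate_hz
  out <- purrr::imap_dfr(as.list(pressure_steps_mmHg), function(p, i) {
    tibble::tibble(
      step = i,
      time_s = (i - 1) * hold_duration_s + (seq_len(n_per) - 1) * dt,
      pressure_mmHg = p,
      flow_uL_min = membrane_flow_ulmin(fluid, membrane, p) +
        if (noise_sd_ulmin > 0) stats::rnorm(n_per, 0, noise_sd_ulmin) else 0
    )
  })
  dplyr::select(out, "time_s", "step", "pressure_mmHg", "flow_uL_min")
}
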