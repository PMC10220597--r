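# Independent brute-force integrator for the compartment model: fixed-step
# explicit Euler on the same mass balances, written directly from the rate
# equations (no shared code with simulate_clearance). Times in minutes
# internally, returns concentrations at the requested output times.
euler_clearance <- function(model, drug, duration_s, out_step_s, dt_s) {
  V_p <- model$posterior_volume_ml
  V_a <- model$anterior_volume_ml
  PA_h <- model$hyaloid_transfer_ulmin / 1000
  PA_rcs <- if (is.null(model$rcs_transfer_ulmin)) 0 else model$rcs_transfer_ulmin / 1000
  s <- model$hyaloid_sieving
  Q <- model$aqueous_inflow_ulmin / 1000
  conv <- if (model$inflow_site == "posterior") s * Q else 0

  M_p <- if (drug$injection_site == "posterior") drug$dose_mass_ug else 0
  M_a <- drug$dose_mass_ug - M_p
  out_a <- 0
  out_p <- 0
  dt <- dt_s / 60
  n_steps <- round(duration_s / dt_s)
  keep_every <- round(out_step_s / dt_s)

  times <- numeric(n_steps %/% keep_every + 1)
  cp <- numeric(length(times))
  ca <- numeric(length(times))
  oa <- numeric(length(times))
  op <- numeric(length(times))
  cp[1] <- M_p / V_p
  ca[1] <- M_a / V_a
  j <- 1
  for (i in seq_len(n_steps)) {
    C_p <- M_p / V_p
    C_a <- M_a / V_a
    f <- (conv + PA_h) * C_p - PA_h * C_a
    M_p <- M_p + dt * (-f - PA_rcs * C_p)
    M_a <- M_a + dt * (f - Q * C_a)
    out_a <- out_a + dt * Q * C_a
    out_p <- out_p + dt * PA_rcs * C_p
    if (i %% keep_every == 0) {
      j <- j + 1
      times[j] <- i * dt_s
      cp[j] <- M_p / V_p
      ca[j] <- M_a / V_a
      oa[j] <- out_a
      op[j] <- out_p
    }
  }
  tibble::tibble(time_s = times, conc_posterior_ug_ml = cp,
                 conc_anterior_ug_ml = ca,
                 cleared_anterior_ug = oa, cleared_posterior_ug = op)
}

# standard lab fluid / membranes used across tests
test_fluid <- function() fluid_spec("PBS", 1e-3)

test_membrane <- function(mwco = 300, diameter_m = 20e-3, ...) {
  membrane_spec(mwco, exposed_diameter_m = diameter_m, ...)
}
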