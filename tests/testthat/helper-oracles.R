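# Shared fixtures and independent numerical oracles.

fixture_params <- function(SI = 0.3, sigma = 3) {
  model_parameters(S_I = SI, sigma = sigma)
}

# Classic fixed-step 4th-order Runge-Kutta over the R-level ode_rhs():
# fully independent of both production integrators.
rk4_simulate <- function(params, times, init, dt = 0.01) {
  y <- as.numeric(init)
  t <- times[1]
  out <- matrix(NA_real_, length(times), 4)
  out[1, ] <- y
  for (i in seq_along(times)[-1]) {
    nstep <- ceiling((times[i] - t) / dt)
    h <- (times[i] - t) / nstep
    for (s in seq_len(nstep)) {
      k1 <- ode_rhs(t, y, params)
      k2 <- ode_rhs(t + h / 2, y + h / 2 * k1, params)
      k3 <- ode_rhs(t + h / 2, y + h / 2 * k2, params)
      k4 <- ode_rhs(t + h, y + h * k3, params)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  out
}

# noise-free observation straight off the forward model
noise_free_obs <- function(SI, sigma, G_fast = 90, id = "nf") {
  generate_ogtt_observation(sigma, SI, noise_sd_glucose = 0,
                            G_fast = G_fast, patient_id = id, seed = 1)
}

# hand-built degenerate chain object for bookkeeping tests
constant_chain <- function(SI, sigma, n, burn_in, with_insulin = TRUE) {
  s <- cbind(S_I = rep(SI, n), sigma = rep(sigma, n))
  structure(list(samples = s, log_posterior = rep(0, n),
                 acceptance_rate = 0.3, burn_in = burn_in,
                 with_insulin = with_insulin, patient_id = "const",
                 seed = 1L),
            class = "chain")
}

# all-normal post-operative events spanning the 6-18-month window
ngm_events <- function(surgery = as.Date("2015-06-01")) {
  mo <- function(m) surgery + round(m * 30.44)
  postop_events(
    hba1c = data.frame(date = mo(c(8, 14)), value = c(5.2, 5.4)),
    ogtt_g0 = data.frame(date = mo(12), value = 90),
    ogtt_g120 = data.frame(date = mo(12), value = 120),
    encounters = data.frame(date = mo(c(7, 10, 13, 16)), codes = rep("", 4))
  )
}
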