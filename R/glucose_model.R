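#' Hepatic glucose production
#'
#' A saturating, strictly decreasing function of plasma insulin and hepatic
#' insulin sensitivity:
#' `HGP(I) = hgp_max / (1 + hepa_SI * (I / I_half)^h_pow)`.
#' The plateau `hgp_max` is attained at `I = 0`; for `I > 0` the value is
#' strictly decreasing in both `I` and `hepa_SI`.
#'
#' @param I plasma insulin, uIU/mL (vectorised; must be non-negative).
#' @param params a [model_parameters()] object.
#' @return flux in mg/dL/min.
#' @export
hepatic_glucose_production <- function(I, params) {
  if (any(!is.finite(I)) || any(I < 0)) stop("insulin must be finite and non-negative")
  hc <- params$hgp_coeffs
  hc$hgp_max / (1 + params$hepa_SI * (I / hc$I_half)^hc$h_pow)
}

#' Oral glucose appearance flux
#'
#' Gamma-density-shaped rate of glucose appearance in plasma after the oral
#' dose: unimodal, zero at `t = 0`, with mode at `appearance_peak_min` and
#' total time-integral `dose_g * 1000 * absorbed_fraction / glucose_vol_dl`
#' (mg/dL).
#'
#' @param t time since dose, minutes (vectorised; non-negative).
#' @param input the `ogtt_input` component of [model_parameters()].
#' @return flux in mg/dL/min.
#' @export
ogtt_flux <- function(t, input) {
  if (any(!is.finite(t)) || any(t < 0)) stop("time must be finite and non-negative")
  shape <- input$appearance_shape
  scale <- input$appearance_peak_min / (shape - 1)
  total <- input$dose_g * 1000 * input$absorbed_fraction / input$glucose_vol_dl
  total * stats::dgamma(t, shape = shape, scale = scale)
}

#' Insulin secretion rate
#'
#' `ISR = C_ISR(G, gamma) * N5`: linear in the primed vesicle pool and
#' increasing in glucose through the calcium-dependent fusion rate.
#'
#' @param G plasma glucose, mg/dL (`> 0`).
#' @param N5 primed vesicles at the membrane (`>= 0`).
#' @param params a [model_parameters()] object.
#' @return secretion rate (vesicle-insulin units per minute).
#' @export
insulin_secretion_rate <- function(G, N5, params) {
  stopifnot(all(G > 0), all(N5 >= 0))
  exocytosis_coefficients(G, params)$C_ISR * N5
}

#' Right-hand side of the fast-timescale ODE system
#'
#' State is `(G, I, N5, N6)`.  Glucose follows
#' `dG/dt = OGTT(t) + HGP(I) - (E_G0 + si_scale * S_I * I) * G`,
#' insulin `dI/dt = (beta/V) * ISR - k * I`, and the vesicle pools follow the
#' linear exocytosis subsystem (see [exocytosis_coefficients()]).  `gamma`
#' and `sigma` are constants on the OGTT timescale: their slow dynamics are
#' not solved here.
#'
#' @param t time, minutes.
#' @param state numeric vector `c(G, I, N5, N6)`.
#' @param params a [model_parameters()] object.
#' @return numeric vector of the four time-derivatives.
#' @export
ode_rhs <- function(t, state, params) {
  if (any(!is.finite(state))) stop("non-finite model state")
  G <- state[[1]]; I <- state[[2]]; N5 <- state[[3]]; N6 <- state[[4]]
  co <- exocytosis_coefficients(G, params)
  dG <- ogtt_flux(t, params$ogtt_input) +
    hepatic_glucose_production(I, params) -
    (params$E_G0 + params$si_scale * params$S_I * I) * G
  dI <- (params$beta / params$V) * co$C_ISR * N5 - params$k * I
  dN5 <- co$c55 * N5 + co$c56 * N6
  dN6 <- co$c60 + co$c65 * N5 + co$c66 * N6
  c(dG = dG, dI = dI, dN5 = dN5, dN6 = dN6)
}

#' Fasting steady state of the model
#'
#' Given a fasting glucose `G_fast`, solves the insulin and vesicle
#' equations for their unique steady state (`dI/dt = dN5/dt = dN6/dt = 0`)
#' in closed form, and (by default) re-anchors the hepatic glucose
#' production plateau so that `dG/dt = 0` as well, i.e. basal HGP balances
#' basal clearance at the patient's fasting glucose.  The calibrated
#' parameter set is attached as attribute `"params"`.
#'
#' @param params a [model_parameters()] object.
#' @param G_fast fasting glucose, mg/dL, in (40, 400).
#' @param calibrate_hgp logical; re-anchor `hgp_coeffs$hgp_max` (default TRUE).
#' @return named numeric state `c(G, I, N5, N6)` with attribute `"params"`
#'   (the possibly recalibrated `model_parameters`).
#' @export
fasting_steady_state <- function(params, G_fast, calibrate_hgp = TRUE) {
  stopifnot(G_fast > 40, G_fast < 400)
  co <- exocytosis_coefficients(G_fast, params)
  # N5 = -(c56/c55) N6 ; c60 + c65 N5 + c66 N6 = 0
  ratio <- -co$c56 / co$c55              # N5 per N6, > 0
  denom <- -(co$c66 + co$c65 * ratio)    # > 0 for admissible coefficients
  if (!is.finite(denom) || denom <= 0) {
    stop("no admissible steady state: vesicle subsystem (dN6/dt) has no stable root")
  }
  N6 <- co$c60 / denom
  N5 <- ratio * N6
  I <- (params$beta / (params$V * params$k)) * co$C_ISR * N5
  if (calibrate_hgp) {
    hc <- params$hgp_coeffs
    clearance <- (params$E_G0 + params$si_scale * params$S_I * I) * G_fast
    params$hgp_coeffs$hgp_max <-
      clearance * (1 + params$hepa_SI * (I / hc$I_half)^hc$h_pow)
  }
  state <- c(G = G_fast, I = I, N5 = N5, N6 = N6)
  resid <- ode_rhs(0, state, zero_dose(params))[if (calibrate_hgp) 1:4 else 2:4]
  if (sqrt(sum(resid^2)) >= 1e-8) {
    stop("steady-state residual too large in equation(s): ",
         paste(names(resid)[abs(resid) > 1e-9], collapse = ", "))
  }
  structure(state, params = params)
}

# Copy of params with the oral dose removed (fasting conditions).
zero_dose <- function(params) {
  params$ogtt_input$dose_g <- 0
  params
}

#' Simulate the model over an OGTT
#'
#' Integrates the four-state system with a stiff-capable adaptive solver
#' (deSolve's lsoda; `method = "rk45"` instead uses the package's compiled
#' embedded Cash--Karp integrator, the one driving the MCMC likelihood).
#' Both use relative tolerance 1e-6 and absolute tolerance 1e-8.
#'
#' @param params a [model_parameters()] object.
#' @param times ascending times in `[0, 240]` minutes at which states are
#'   reported; 0 is prepended if absent.
#' @param init initial state `c(G, I, N5, N6)`; defaults to the fasting
#'   steady state at `init_G` (in which case the HGP-calibrated parameters
#'   are used).
#' @param init_G fasting glucose used when `init` is missing.
#' @param method `"lsoda"` (default) or `"rk45"`.
#' @return a `trajectory`: data.frame with columns `time_min`,
#'   `glucose_mgdl`, `insulin_uIUml`, `n5`, `n6`.
#' @export
#' @examples
#' tr <- simulate_ogtt(model_parameters(S_I = 0.3, sigma = 3),
#'                     times = c(0, 30, 60, 120), init_G = 90)
#' tr$glucose_mgdl
simulate_ogtt <- function(params, times, init = NULL, init_G = 90,
                          method = c("lsoda", "rk45")) {
  method <- match.arg(method)
  stopifnot(all(diff(times) > 0), all(times >= 0), all(times <= 240))
  if (is.null(init)) {
    init <- fasting_steady_state(params, init_G)
    params <- attr(init, "params")
  }
  if (any(!is.finite(init)) || init[[1]] <= 0) stop("invalid initial state")
  solve_times <- if (times[1] > 0) c(0, times) else times
  if (method == "lsoda") {
    sol <- deSolve::ode(
      y = c(G = init[[1]], I = init[[2]], N5 = init[[3]], N6 = init[[4]]),
      times = solve_times,
      func = function(t, y, p) list(ode_rhs(t, y, p)),
      parms = params, method = "lsoda", rtol = 1e-6, atol = 1e-8
    )
    if (attr(sol, "istate")[1] < 0) {
      stop("integration failure at t = ", utils::tail(sol[, 1], 1),
           "; last state: ", paste(signif(utils::tail(sol, 1)[-1], 6), collapse = ", "))
    }
    out <- as.data.frame(sol)
  } else {
    m <- simulate_rk45_cpp(params_for_cpp(params), as.numeric(init), solve_times)
    out <- data.frame(time = solve_times, G = m[, 1], I = m[, 2],
                      N5 = m[, 3], N6 = m[, 4])
  }
  keep <- out$time %in% times
  traj <- data.frame(
    time_min = out$time[keep],
    glucose_mgdl = out$G[keep],
    insulin_uIUml = out$I[keep],
    n5 = out$N5[keep],
    n6 = out$N6[keep]
  )
  if (any(!is.finite(as.matrix(traj)))) stop("non-finite trajectory")
  class(traj) <- c("trajectory", "data.frame")
  traj
}

# Flatten a model_parameters object into the numeric vector layout the
# compiled integrator expects.  Order must match params_from_vector in src/.
params_for_cpp <- function(p) {
  ec <- p$exo_coeffs; hc <- p$hgp_coeffs; oi <- p$ogtt_input
  as.numeric(c(
    p$S_I, p$sigma, p$gamma, p$E_G0, p$si_scale, p$k, p$V, p$beta,
    p$hepa_SI, p$r2_0,
    ec$cisr_max, ec$K_half, ec$K_slope, ec$r2_base, ec$r_unprime,
    ec$r_undock, ec$dock_base, ec$dock_max,
    hc$hgp_max, hc$I_half, hc$h_pow,
    oi$dose_g, oi$absorbed_fraction, oi$glucose_vol_dl,
    oi$appearance_shape, oi$appearance_peak_min
  ))
}

#' Write a trajectory to delimited text
#'
#' @param traj a trajectory from [simulate_ogtt()].
#' @param file output path.
#' @export
write_trajectory <- function(traj, file) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
}
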