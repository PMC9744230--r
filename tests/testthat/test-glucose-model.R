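test_that("hepatic glucose production is positive, bounded, decreasing", {
  p <- fixture_params()
  expect_equal(hepatic_glucose_production(0, p), p$hgp_coeffs$hgp_max)
  expect_lt(hepatic_glucose_production(50, p), hepatic_glucose_production(5, p))
  Is <- seq(0, 200, by = 5)
  v <- hepatic_glucose_production(Is, p)
  expect_true(all(v > 0))
  expect_true(all(diff(v) < 0))
  expect_true(all(v <= p$hgp_coeffs$hgp_max))
  # decreasing in hepatic insulin sensitivity at fixed positive insulin
  p_hi <- fixture_params(); p_hi$hepa_SI <- 2
  expect_lt(hepatic_glucose_production(20, p_hi),
            hepatic_glucose_production(20, p))
  expect_error(hepatic_glucose_production(-1, p), "non-negative")
})

test_that("HGP balances clearance exactly at the calibrated fasting state", {
  p <- fixture_params()
  st <- fasting_steady_state(p, 90)
  pc <- attr(st, "params")
  clearance <- function(I) (pc$E_G0 + pc$si_scale * pc$S_I * I) * 90
  # root-finding oracle: the insulin at which HGP balances clearance
  root <- stats::uniroot(function(I) hepatic_glucose_production(I, pc) - clearance(I),
                         c(1e-6, 500), tol = 1e-12)$root
  expect_equal(root, unname(st["I"]), tolerance = 1e-6)
  expect_equal(hepatic_glucose_production(st[["I"]], pc), clearance(st[["I"]]),
               tolerance = 1e-10)
})

test_that("oral glucose appearance is unimodal with the configured mass", {
  inp <- fixture_params()$ogtt_input
  expect_equal(ogtt_flux(0, inp), 0)
  inp0 <- inp; inp0$dose_g <- 0
  expect_equal(ogtt_flux(seq(0, 240, 10), inp0), rep(0, 25))
  # quadrature oracle for total appeared glucose
  total <- stats::integrate(function(t) ogtt_flux(t, inp), 0, 240,
                            rel.tol = 1e-10)$value
  expected <- inp$dose_g * 1000 * inp$absorbed_fraction / inp$glucose_vol_dl
  expect_lt(abs(total - expected) / expected, 0.001)
  # grid-scan oracle: exactly one local maximum
  tt <- seq(0, 240, by = 0.25)
  v <- ogtt_flux(tt, inp)
  expect_true(all(v >= 0))
  peaks <- sum(diff(sign(diff(v))) == -2)
  expect_equal(peaks, 1)
  expect_equal(tt[which.max(v)], inp$appearance_peak_min, tolerance = 0.3)
  expect_error(ogtt_flux(-5, inp), "non-negative")
})

test_that("insulin secretion rate is linear in N5 and increasing in glucose", {
  p <- fixture_params()
  expect_equal(insulin_secretion_rate(100, 0, p), 0)
  expect_gt(insulin_secretion_rate(200, 40, p), insulin_secretion_rate(80, 40, p))
  expect_equal(insulin_secretion_rate(120, 80, p),
               2 * insulin_secretion_rate(120, 40, p))
  # increasing in G across the physiological range
  isr <- insulin_secretion_rate(seq(50, 300, 10), 40, p)
  expect_true(all(diff(isr) > 0))
})

test_that("ode_rhs matches a hand-coded duplicate of the model equations", {
  p <- fixture_params(SI = 0.7, sigma = 2.2)
  state <- c(G = 140, I = 35, N5 = 50, N6 = 160)
  got <- ode_rhs(17, state, p)
  # independent re-derivation, written out in full
  ec <- p$exo_coeffs
  kap <- 1 / (1 + exp(-(140 - ec$K_half * (1 + p$gamma)) / ec$K_slope))
  C_ISR <- ec$cisr_max * kap
  r2 <- p$r2_0 * (ec$r2_base + kap)
  flux <- (p$ogtt_input$dose_g * 1000 * p$ogtt_input$absorbed_fraction /
             p$ogtt_input$glucose_vol_dl) *
    stats::dgamma(17, shape = p$ogtt_input$appearance_shape,
                  scale = p$ogtt_input$appearance_peak_min /
                    (p$ogtt_input$appearance_shape - 1))
  hgp <- p$hgp_coeffs$hgp_max /
    (1 + p$hepa_SI * (35 / p$hgp_coeffs$I_half)^p$hgp_coeffs$h_pow)
  expect_equal(got[["dG"]],
               flux + hgp - (p$E_G0 + p$si_scale * p$S_I * 35) * 140,
               tolerance = 1e-12)
  expect_equal(got[["dI"]], (p$beta / p$V) * C_ISR * 50 - p$k * 35,
               tolerance = 1e-12)
  expect_equal(got[["dN5"]], -(C_ISR + ec$r_unprime) * 50 + r2 * 160,
               tolerance = 1e-12)
  expect_equal(got[["dN6"]],
               p$sigma * (ec$dock_base + ec$dock_max * kap) +
                 ec$r_unprime * 50 - (r2 + ec$r_undock) * 160,
               tolerance = 1e-12)
  expect_error(ode_rhs(0, c(NA, 1, 1, 1), p), "non-finite")
})

test_that("derivatives vanish at the fasting steady state; HGP term drives dG when clearance is removed", {
  p <- fixture_params()
  st <- fasting_steady_state(p, 90)
  pc <- attr(st, "params")
  pc$ogtt_input$dose_g <- 0
  expect_true(all(abs(ode_rhs(0, st, pc)) < 1e-8))
  # remove all clearance: glucose must rise at the HGP rate
  p0 <- unclass(fixture_params())
  p0$S_I <- 0; p0$E_G0 <- 0
  p0$ogtt_input$dose_g <- 0
  d <- ode_rhs(0, c(G = 90, I = 10, N5 = 40, N6 = 140), p0)
  expect_equal(d[["dG"]], hepatic_glucose_production(10, p0))
  expect_gt(d[["dG"]], 0)
})

test_that("fasting steady state agrees with a damped fixed-point oracle", {
  p <- fixture_params(SI = 0.5, sigma = 4)
  st <- fasting_steady_state(p, 95)
  co <- exocytosis_coefficients(95, p)
  N5 <- 1; N6 <- 1
  for (i in 1:500) {
    N6_new <- (co$c60 + co$c65 * N5) / (-co$c66)
    N5_new <- co$c56 * N6_new / (-co$c55)
    N5 <- 0.5 * N5 + 0.5 * N5_new
    N6 <- 0.5 * N6 + 0.5 * N6_new
  }
  I <- (p$beta / (p$V * p$k)) * co$C_ISR * N5
  expect_equal(unname(st["N5"]), N5, tolerance = 1e-6)
  expect_equal(unname(st["N6"]), N6, tolerance = 1e-6)
  expect_equal(unname(st["I"]), I, tolerance = 1e-6)
  # dI/dt = 0 rearranged
  expect_equal(unname(st["I"]),
               (p$beta / (p$V * p$k)) * insulin_secretion_rate(95, st[["N5"]], p),
               tolerance = 1e-10)
})

test_that("zero-dose simulation from the fasting steady state stays flat", {
  p <- fixture_params()
  st <- fasting_steady_state(p, 90)
  pc <- attr(st, "params")
  pc$ogtt_input$dose_g <- 0
  tr <- simulate_ogtt(pc, times = seq(0, 240, 20), init = st)
  expect_true(all(abs(tr$glucose_mgdl - 90) < 0.5))
  # gamma and sigma are untouched by simulation
  expect_identical(pc$gamma, fixture_params()$gamma)
  expect_identical(pc$sigma, 3)
})

test_that("comparative statics: higher S_I or sigma lowers the glucose AUC", {
  auc <- function(SI, sigma) {
    tr <- simulate_ogtt(model_parameters(S_I = SI, sigma = sigma),
                        times = seq(0, 120, 10), init_G = 90)
    sum(diff(tr$time_min) * zoo_mid(tr$glucose_mgdl))
  }
  zoo_mid <- function(x) (x[-1] + x[-length(x)]) / 2
  g_auc_si <- vapply(c(0.15, 0.3, 0.6), auc, 0, sigma = 3)
  expect_true(all(diff(g_auc_si) < 0))
  g_auc_sg <- vapply(c(1.5, 3, 6), function(s) auc(0.3, s), 0)
  expect_true(all(diff(g_auc_sg) < 0))
  # higher sigma raises the insulin AUC
  iauc <- function(sigma) {
    tr <- simulate_ogtt(model_parameters(S_I = 0.3, sigma = sigma),
                        times = seq(0, 120, 10), init_G = 90)
    sum(diff(tr$time_min) * zoo_mid(tr$insulin_uIUml))
  }
  expect_true(all(diff(vapply(c(1.5, 3, 6), iauc, 0)) > 0))
})

test_that("adaptive solvers agree with a small-fixed-step RK4 oracle", {
  set.seed(31)
  b <- parameter_bounds()
  for (r in 1:10) {
    p <- model_parameters(S_I = runif(1, 0.05, 1.5), sigma = runif(1, 0.5, 8))
    st <- fasting_steady_state(p, runif(1, 80, 100))
    pc <- attr(st, "params")
    times <- c(0, 30, 60, 120)
    lsoda <- simulate_ogtt(pc, times, init = st, method = "lsoda")
    rk45 <- simulate_ogtt(pc, times, init = st, method = "rk45")
    oracle <- rk4_simulate(pc, times, st, dt = 0.05)
    expect_lt(max(abs(lsoda$glucose_mgdl - oracle[, 1])), 0.1)
    expect_lt(max(abs(rk45$glucose_mgdl - oracle[, 1])), 0.1)
    expect_lt(max(abs(lsoda$glucose_mgdl - rk45$glucose_mgdl)), 0.05)
  }
})

test_that("simulate_ogtt is deterministic and validates its inputs", {
  p <- fixture_params()
  a <- simulate_ogtt(p, c(0, 30, 60, 120), init_G = 90)
  b <- simulate_ogtt(p, c(0, 30, 60, 120), init_G = 90)
  expect_identical(a, b)
  expect_error(simulate_ogtt(p, c(30, 10), init_G = 90))
  expect_error(simulate_ogtt(p, c(0, 400), init_G = 90))
})

test_that("model parameter constructor enforces bounds and loads defaults", {
  expect_error(model_parameters(S_I = 4), "S_I")
  expect_error(model_parameters(S_I = 0.3, sigma = 11), "sigma")
  p <- model_parameters(S_I = 0.3, sigma = 3, k = 0.2)
  expect_equal(p$k, 0.2)
  expect_equal(p$gamma, -0.076)
  expect_equal(p$E_G0, 0.0118)
  expect_error(model_parameters(S_I = 0.3, sigma = 3, nope = 1), "unknown")
  # coefficient functions are finite at admissible inputs
  for (G in c(50, 90, 150, 300)) {
    expect_true(all(vapply(exocytosis_coefficients(G, p), is.finite, TRUE)))
  }
})
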