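test_that("log-posterior: uniform prior support and Gaussian error model", {
  obs <- noise_free_obs(0.3, 3)
  cfg <- inference_config(seed = 1)
  expect_identical(log_posterior(c(4.0, 1.0), obs, cfg), -Inf)
  expect_identical(log_posterior(c(0.3, 12), obs, cfg), -Inf)
  # zero-residual fit: value is exactly the sum of Gaussian normalisations
  lp <- log_posterior(c(0.3, 3), obs, cfg)
  m <- length(obs$times)
  sd_i <- rep(max(cfg$insulin_noise_frac * mean(obs$insulin),
                  cfg$insulin_noise_floor), m)
  expected <- m * (-0.5 * log(2 * pi * cfg$noise_sd_glucose^2)) +
    sum(-0.5 * log(2 * pi * sd_i^2))
  expect_equal(lp, expected, tolerance = 1e-6)
  # glucose-only variant
  cfg_g <- inference_config(use_insulin = FALSE, seed = 1)
  obs_g <- obs; obs_g$insulin <- NULL
  lp_g <- log_posterior(c(0.3, 3), obs_g, cfg_g)
  expect_lte(lp_g, m * (-0.5 * log(2 * pi * cfg$noise_sd_glucose^2)) + 1e-6)
})

test_that("grid-search oracle: noise-free log-posterior peaks nearest the truth", {
  truth <- c(0.3, 3.0)
  obs <- noise_free_obs(truth[1], truth[2])
  cfg <- inference_config(seed = 1)
  b <- parameter_bounds()
  g1 <- seq(b$S_I[1], b$S_I[2], length.out = 21)
  g2 <- seq(b$sigma[1], b$sigma[2], length.out = 21)
  lp <- outer(seq_along(g1), seq_along(g2), Vectorize(function(i, j) {
    log_posterior(c(g1[i], g2[j]), obs, cfg)
  }))
  best <- arrayInd(which.max(lp), dim(lp))
  expect_equal(best[1], which.min(abs(g1 - truth[1])))
  expect_equal(best[2], which.min(abs(g2 - truth[2])))
})

test_that("chains are reproducible and respect the parameter bounds", {
  obs <- generate_ogtt_observation(3, 0.3, noise_sd_glucose = 2, seed = 4)
  cfg <- inference_config(n_iter = 4000, burn_in = 1000, seed = 42)
  ch1 <- run_rwmh(obs, cfg)
  ch2 <- run_rwmh(obs, cfg)
  expect_identical(ch1$samples, ch2$samples)
  b <- parameter_bounds()
  expect_true(all(ch1$samples[, "S_I"] >= b$S_I[1] &
                    ch1$samples[, "S_I"] <= b$S_I[2]))
  expect_true(all(ch1$samples[, "sigma"] >= b$sigma[1] &
                    ch1$samples[, "sigma"] <= b$sigma[2]))
  expect_gte(ch1$acceptance_rate, 0)
  expect_lte(ch1$acceptance_rate, 1)
})

test_that("a flat target yields uniform marginals over the bounds", {
  # astronomically wide noise makes the likelihood constant inside the box
  obs <- noise_free_obs(0.3, 3)
  cfg <- inference_config(n_iter = 20000, burn_in = 4000, seed = 9,
                          noise_sd_glucose = 1e9,
                          insulin_noise_floor = 1e9)
  ch <- run_rwmh(obs, cfg)
  kept <- ch$samples[-(1:4000), ]
  thin <- kept[seq(1, nrow(kept), by = 25), ]
  b <- parameter_bounds()
  ks1 <- stats::ks.test(thin[, 1], "punif", b$S_I[1], b$S_I[2])
  ks2 <- stats::ks.test(thin[, 2], "punif", b$sigma[1], b$sigma[2])
  expect_gt(ks1$p.value, 0.01)
  expect_gt(ks2$p.value, 0.01)
})

test_that("posterior recovers a synthetic patient and stays interior", {
  obs <- generate_ogtt_observation(3.0, 0.3, noise_sd_glucose = 2,
                                   insulin_noise_frac = 0.05, seed = 7)
  cfg <- inference_config(n_iter = 50000, burn_in = 5000, seed = 11)
  ch <- run_rwmh(obs, cfg)
  s <- summarize_posterior(ch)
  expect_lt(abs(s$mean_SI - 0.3), 2 * s$sd_SI)
  expect_lt(abs(s$mean_sigma - 3.0), 2 * s$sd_sigma)
  expect_gte(ch$acceptance_rate, 0.1)
  expect_lte(ch$acceptance_rate, 0.6)
  # well-identified posterior mode sits away from both bounds
  d <- stats::density(ch$samples[-(1:5000), "S_I"])
  mode_SI <- d$x[which.max(d$y)]
  b <- parameter_bounds()
  expect_gt(mode_SI - b$S_I[1], ch$proposal_sd[1])
  expect_gt(b$S_I[2] - mode_SI, ch$proposal_sd[1])
})

test_that("independent chains agree on the same patient", {
  obs <- generate_ogtt_observation(3.0, 0.3, noise_sd_glucose = 2,
                                   insulin_noise_frac = 0.05, seed = 8)
  s1 <- summarize_posterior(run_rwmh(obs, inference_config(20000, 4000, seed = 1)))
  s2 <- summarize_posterior(run_rwmh(obs, inference_config(20000, 4000, seed = 2)))
  pooled_SI <- sqrt((s1$sd_SI^2 + s2$sd_SI^2) / 2)
  pooled_sg <- sqrt((s1$sd_sigma^2 + s2$sd_sigma^2) / 2)
  expect_lt(abs(s1$mean_SI - s2$mean_SI), 0.5 * pooled_SI)
  expect_lt(abs(s1$mean_sigma - s2$mean_sigma), 0.5 * pooled_sg)
})

test_that("without-insulin fits ignore the insulin observations entirely", {
  obs <- generate_ogtt_observation(3, 0.3, noise_sd_glucose = 2, seed = 5)
  cfg <- inference_config(n_iter = 3000, burn_in = 500, seed = 3,
                          use_insulin = FALSE)
  ch1 <- run_rwmh(obs, cfg)
  obs2 <- obs
  obs2$insulin <- obs$insulin * 10 + 7
  ch2 <- run_rwmh(obs2, cfg)
  expect_identical(ch1$samples, ch2$samples)
  expect_false(summarize_posterior(ch1)$with_insulin)
})

test_that("posterior summaries use retained samples and per-sample products", {
  ch <- constant_chain(2, 3, 1000, 100)
  s <- summarize_posterior(ch)
  expect_equal(s$mean_SI, 2)
  expect_equal(s$sd_SI, 0)
  expect_equal(s$mean_product, 6)
  expect_equal(s$n_retained, 900)
  # full-protocol bookkeeping: 500,000 iterations less 50,000 burn-in
  big <- constant_chain(1, 1, 500000, 50000)
  expect_equal(summarize_posterior(big)$n_retained, 450000)
  # per-sample product, not product of means
  two <- constant_chain(1, 2, 2, 0)
  two$samples <- cbind(S_I = c(1, 3), sigma = c(2, 4))
  s2 <- summarize_posterior(two, burn_in = 0)
  expect_equal(s2$mean_product, 7)       # (1*2 + 3*4)/2
  expect_false(isTRUE(all.equal(s2$mean_product, s2$mean_SI * s2$mean_sigma)))
  expect_error(summarize_posterior(two, burn_in = 2), "retained")
})

test_that("autocorrelation is normalised and matches closed forms", {
  set.seed(60)
  wn <- constant_chain(0, 0, 20000, 0)
  wn$samples <- cbind(S_I = rnorm(20000), sigma = rnorm(20000))
  ac <- chain_autocorrelation(wn, max_lag = 50)
  expect_equal(unname(ac[1, ]), c(1, 1))
  expect_true(all(abs(ac[-1, ]) < 3 / sqrt(20000)))
  # AR(1) with coefficient 0.9: r_k ~ 0.9^k
  n <- 100000
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  arch <- constant_chain(0, 0, n, 0)
  arch$samples <- cbind(S_I = ar, sigma = ar)
  ac2 <- chain_autocorrelation(arch, max_lag = 10)
  expect_true(all(abs(ac2[2:11, 1] - 0.9^(1:10)) < 0.05))
  expect_error(chain_autocorrelation(wn, max_lag = 20000), "shorter")
})

test_that("cohort fitting is deterministic, keyed by patient, failure-tolerant", {
  empty <- fit_cohort(list(), inference_config(seed = 1))
  expect_equal(nrow(empty), 0)
  set.seed(12)
  obs <- lapply(1:3, function(i) {
    generate_ogtt_observation(3, 0.3, noise_sd_glucose = 2,
                              patient_id = paste0("P", i))
  })
  cfg <- inference_config(n_iter = 2000, burn_in = 400, seed = 77)
  s1 <- fit_cohort(obs, cfg)
  s2 <- fit_cohort(obs, cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 3)
  expect_setequal(s1$patient_id, c("P1", "P2", "P3"))
  obs_dup <- obs
  obs_dup[[2]]$patient_id <- "P1"
  expect_error(fit_cohort(obs_dup, cfg), "duplicate")
})

test_that("two-group cohorts separate in posterior-mean insulin sensitivity", {
  set.seed(14)
  lo <- lapply(1:10, function(i) {
    generate_ogtt_observation(1.596, 0.155, noise_sd_glucose = 5,
                              patient_id = paste0("L", i))
  })
  hi <- lapply(1:10, function(i) {
    generate_ogtt_observation(3.424, 0.356, noise_sd_glucose = 5,
                              patient_id = paste0("H", i))
  })
  cfg <- inference_config(n_iter = 3000, burn_in = 600, seed = 15)
  s <- fit_cohort(c(lo, hi), cfg)
  grp <- substr(s$patient_id, 1, 1)
  expect_lt(median(s$mean_SI[grp == "L"]), median(s$mean_SI[grp == "H"]))
  w <- stats::wilcox.test(s$mean_SI[grp == "L"], s$mean_SI[grp == "H"],
                          alternative = "less")
  expect_lt(w$p.value, 0.05)
})

test_that("OGTT tables round-trip through delimited text", {
  obs <- list(
    ogtt_observation("A", c(90, 150, 140, 100), c(10, 50, 60, 30)),
    ogtt_observation("B", c(95, 160, 150, 110))
  )
  f <- tempfile(fileext = ".csv")
  write_ogtt(obs, f)
  back <- read_ogtt(f)
  expect_equal(back[["A"]]$glucose, obs[[1]]$glucose)
  expect_equal(back[["A"]]$insulin, obs[[1]]$insulin)
  expect_null(back[["B"]]$insulin)
  unlink(f)
})
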