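#' One patient's OGTT observation
#'
#' @param patient_id identifier (scalar).
#' @param glucose glucose in mg/dL at the four sampling times.
#' @param insulin optional insulin in uIU/mL at the same times; either
#'   absent entirely or present at all four times.
#' @param times sampling times in minutes (default `c(0, 30, 60, 120)`).
#' @return an `ogtt_observation` object.
#' @export
ogtt_observation <- function(patient_id, glucose, insulin = NULL,
                             times = c(0, 30, 60, 120)) {
  stopifnot(length(times) == length(glucose), all(diff(times) > 0),
            all(is.finite(glucose)), all(glucose > 0))
  if (!is.null(insulin)) {
    stopifnot(length(insulin) == length(glucose), all(is.finite(insulin)),
              all(insulin >= 0))
  }
  structure(list(patient_id = patient_id, times = times,
                 glucose = glucose, insulin = insulin),
            class = "ogtt_observation")
}

#' MCMC inference configuration
#'
#' Defaults follow the full-scale protocol (500,000 iterations, 50,000
#' burn-in, uniform priors on `S_I` in `[0.005, 3]` and `sigma` in
#' `[0.01, 10]`, Gaussian error model).  Desk-scale runs simply pass smaller
#' `n_iter`/`burn_in`.
#'
#' @param n_iter total chain length.
#' @param burn_in iterations discarded before summarisation (`< n_iter`).
#' @param proposal_scales initial per-parameter proposal SDs `c(S_I, sigma)`.
#' @param adapt logical: rescale proposals every 500 burn-in iterations
#'   toward the 0.2--0.5 acceptance band, frozen afterwards.
#' @param noise_sd_glucose glucose measurement noise SD, mg/dL.
#' @param insulin_noise_frac,insulin_noise_floor insulin noise SD is
#'   `max(frac * observed, floor)` uIU/mL per time point.
#' @param use_insulin include the insulin likelihood (overline variants in
#'   reports use `FALSE`).
#' @param I0_fallback initial insulin (uIU/mL) when fitting without
#'   measured insulin.
#' @param seed integer RNG seed.
#' @return an `inference_config` object.
#' @export
inference_config <- function(n_iter = 500000, burn_in = 50000,
                             proposal_scales = c(S_I = 0.1, sigma = 0.4),
                             adapt = TRUE, noise_sd_glucose = 5,
                             insulin_noise_frac = 0.15,
                             insulin_noise_floor = 2,
                             use_insulin = TRUE, I0_fallback = 5.63,
                             seed = 1L) {
  b <- parameter_bounds()
  stopifnot(burn_in < n_iter, n_iter > 0, noise_sd_glucose > 0,
            insulin_noise_floor > 0, all(proposal_scales > 0))
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 bounds_SI = b$S_I, bounds_sigma = b$sigma,
                 proposal_scales = proposal_scales, adapt = adapt,
                 noise_sd_glucose = noise_sd_glucose,
                 insulin_noise_frac = insulin_noise_frac,
                 insulin_noise_floor = insulin_noise_floor,
                 use_insulin = use_insulin, I0_fallback = I0_fallback,
                 seed = as.integer(seed)),
            class = "inference_config")
}

# Likelihood plumbing shared by log_posterior and run_rwmh.
likelihood_args <- function(obs, cfg) {
  use_ins <- isTRUE(cfg$use_insulin) && !is.null(obs$insulin)
  if (isTRUE(cfg$use_insulin) && is.null(obs$insulin)) use_ins <- FALSE
  i_obs <- if (use_ins) obs$insulin else numeric(length(obs$times))
  # constant per-patient insulin SD (fraction of the mean observed level):
  # weighting each point by its own noisy value would correlate noise with
  # weight and bias the fit toward low-insulin trajectories
  sd_i <- rep(max(cfg$insulin_noise_frac * mean(i_obs), cfg$insulin_noise_floor),
              length(obs$times))
  I0 <- if (use_ins) obs$insulin[1] else cfg$I0_fallback
  list(use_insulin = use_ins, i_obs = i_obs, sd_i = sd_i, I0 = I0)
}

#' Log-posterior of (S_I, sigma) for one patient
#'
#' Uniform priors inside the parameter bounds (`-Inf` outside) plus
#' independent Gaussian log-densities of the residuals between observed and
#' simulated glucose (and insulin, when used) at the OGTT times.  The
#' forward simulation starts at the fasting steady state computed at the
#' patient's measured fasting glucose, with initial insulin set to the
#' measured value (with-insulin fits) or the fixed fallback.
#'
#' @param theta numeric `c(S_I, sigma)`.
#' @param obs an [ogtt_observation()].
#' @param cfg an [inference_config()].
#' @param params a [model_parameters()] object holding the fixed constants.
#' @return scalar log-posterior (`-Inf` outside bounds or on simulation
#'   failure).
#' @export
log_posterior <- function(theta, obs, cfg, params = model_parameters()) {
  la <- likelihood_args(obs, cfg)
  log_posterior_cpp(as.numeric(theta), params_for_cpp(params),
                    obs$times, obs$glucose, la$i_obs, la$use_insulin,
                    cfg$noise_sd_glucose, la$sd_i, la$I0,
                    cfg$bounds_SI, cfg$bounds_sigma)
}

#' Run a random-walk Metropolis-Hastings chain for one patient
#'
#' Joint bivariate Gaussian proposals with diagonal covariance; standard
#' accept/reject; chain starts at the bound-box midpoint; deterministic
#' given `cfg$seed`.
#'
#' @inheritParams log_posterior
#' @return a `chain` object: list with `samples` (n_iter x 2 matrix, columns
#'   `S_I`, `sigma`), `log_posterior` trace, post-burn-in `acceptance_rate`,
#'   final `proposal_sd`, `burn_in`, `with_insulin`, `patient_id`, `seed`.
#' @export
run_rwmh <- function(obs, cfg, params = model_parameters()) {
  la <- likelihood_args(obs, cfg)
  set.seed(cfg$seed)
  res <- rwmh_cpp(params_for_cpp(params), obs$times, obs$glucose,
                  la$i_obs, la$use_insulin, cfg$noise_sd_glucose, la$sd_i,
                  la$I0, cfg$bounds_SI, cfg$bounds_sigma,
                  cfg$n_iter, cfg$burn_in, as.numeric(cfg$proposal_scales),
                  cfg$adapt)
  if (is.finite(res$acceptance_rate) && res$acceptance_rate < 0.01) {
    stop("acceptance rate ", signif(res$acceptance_rate, 3),
         " below 0.01 after proposal tuning; rescale proposal_scales")
  }
  colnames(res$samples) <- c("S_I", "sigma")
  structure(list(samples = res$samples, log_posterior = res$log_posterior,
                 acceptance_rate = res$acceptance_rate,
                 proposal_sd = res$proposal_sd, burn_in = cfg$burn_in,
                 with_insulin = la$use_insulin,
                 patient_id = obs$patient_id, seed = cfg$seed),
            class = "chain")
}

#' Summarise a posterior chain
#'
#' Means and SDs of `S_I`, `sigma`, and their per-sample product
#' `sigma * S_I` (summarised sample-by-sample, not mean-times-mean) over
#' the retained (post-burn-in) iterations.
#'
#' @param chain a `chain` from [run_rwmh()].
#' @param burn_in iterations to discard (defaults to the chain's own).
#' @return a one-row data.frame (`posterior_summary`): `patient_id`,
#'   `mean_SI`, `sd_SI`, `mean_sigma`, `sd_sigma`, `mean_product`,
#'   `sd_product`, `n_retained`, `acceptance_rate`, `with_insulin`.
#' @export
summarize_posterior <- function(chain, burn_in = chain$burn_in) {
  n <- nrow(chain$samples)
  if (burn_in >= n) stop("burn-in leaves no retained samples")
  kept <- chain$samples[(burn_in + 1):n, , drop = FALSE]
  prod <- kept[, "S_I"] * kept[, "sigma"]
  out <- data.frame(
    patient_id = if (is.null(chain$patient_id)) NA else chain$patient_id,
    mean_SI = mean(kept[, "S_I"]), sd_SI = stats::sd(kept[, "S_I"]),
    mean_sigma = mean(kept[, "sigma"]), sd_sigma = stats::sd(kept[, "sigma"]),
    mean_product = mean(prod), sd_product = stats::sd(prod),
    n_retained = as.integer(n - burn_in),
    acceptance_rate = chain$acceptance_rate,
    with_insulin = isTRUE(chain$with_insulin),
    stringsAsFactors = FALSE
  )
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Normalised autocorrelation of the retained chain
#'
#' @param chain a `chain` from [run_rwmh()].
#' @param max_lag largest lag (must be below the retained length).
#' @return matrix with `max_lag + 1` rows (lag 0 ... max_lag) and one column
#'   per parameter; lag 0 is exactly 1.
#' @export
chain_autocorrelation <- function(chain, max_lag = 500) {
  kept <- chain$samples[(chain$burn_in + 1):nrow(chain$samples), , drop = FALSE]
  if (nrow(kept) <= max_lag) stop("retained chain shorter than max_lag")
  out <- apply(kept, 2, function(x) {
    as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                          demean = TRUE)$acf)
  })
  rownames(out) <- 0:max_lag
  out
}

#' Fit a whole cohort of OGTT observations
#'
#' Runs [run_rwmh()] + [summarize_posterior()] per patient, with per-patient
#' seeds drawn deterministically from the master seed in `cfg$seed`.
#' Per-patient failures are collected, not fatal.
#'
#' @param observations list of [ogtt_observation()] with unique patient ids.
#' @param cfg an [inference_config()].
#' @param params a [model_parameters()] object.
#' @return data.frame of posterior summaries (one row per successful
#'   patient) with attribute `"failed"` naming any failing patient ids.
#' @export
fit_cohort <- function(observations, cfg, params = model_parameters()) {
  ids <- vapply(observations, function(o) as.character(o$patient_id), "")
  if (anyDuplicated(ids)) stop("duplicate patient ids")
  if (length(observations) == 0) {
    out <- data.frame(patient_id = character(0), mean_SI = numeric(0),
                      sd_SI = numeric(0), mean_sigma = numeric(0),
                      sd_sigma = numeric(0), mean_product = numeric(0),
                      sd_product = numeric(0), n_retained = integer(0),
                      acceptance_rate = numeric(0), with_insulin = logical(0))
    attr(out, "failed") <- character(0)
    return(out)
  }
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, length(observations))
  rows <- vector("list", length(observations))
  failed <- character(0)
  for (i in seq_along(observations)) {
    cfg_i <- cfg
    cfg_i$seed <- seeds[i]
    rows[[i]] <- tryCatch(
      summarize_posterior(run_rwmh(observations[[i]], cfg_i, params)),
      error = function(e) {
        failed <<- c(failed, ids[i])
        NULL
      })
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  attr(out, "failed") <- failed
  out
}

#' Read OGTT observations from delimited text
#'
#' Expects columns `patient_id, t_min, glucose_mgdl, insulin_uIUml`
#' (insulin may be blank throughout a patient).
#'
#' @param file path to a CSV file.
#' @return list of [ogtt_observation()] objects.
#' @export
read_ogtt <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "t_min", "glucose_mgdl") %in% names(d)))
  lapply(split(d, d$patient_id), function(di) {
    di <- di[order(di$t_min), ]
    ins <- di$insulin_uIUml
    if (is.null(ins) || all(is.na(ins))) ins <- NULL
    ogtt_observation(di$patient_id[1], di$glucose_mgdl, ins, di$t_min)
  })
}

#' Write OGTT observations to delimited text
#'
#' @param observations list of [ogtt_observation()].
#' @param file output CSV path.
#' @export
write_ogtt <- function(observations, file) {
  rows <- lapply(observations, function(o) {
    data.frame(patient_id = o$patient_id, t_min = o$times,
               glucose_mgdl = o$glucose,
               insulin_uIUml = if (is.null(o$insulin)) NA else o$insulin)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
}

#' Write posterior summaries to delimited text
#'
#' @param summaries data.frame from [fit_cohort()].
#' @param file output CSV path.
#' @export
write_posterior_summaries <- function(summaries, file) {
  utils::write.csv(as.data.frame(summaries), file, row.names = FALSE)
}
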