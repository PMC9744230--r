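#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the pipeline assumes: ~32%
#' positive prevalence, two latent subpopulations whose (S_I, sigma)
#' medians match the reported group medians (NGM: S_I 0.356, sigma 3.424;
#' IGM: S_I 0.155, sigma 1.596), log-normal within-group spread,
#' forward-model OGTT curves with Gaussian measurement noise, covariates
#' shifted by glycemic group, and a 10% label-noise flip rate.
#'
#' @param n_patients cohort size.
#' @param igm_fraction latent positive prevalence (default 0.318).
#' @param SI_median,sigma_median length-2 named vectors `c(ngm=, igm=)` of
#'   subgroup medians.
#' @param SI_sdlog,sigma_sdlog log-scale SDs of the subgroup distributions.
#' @param noise_sd_glucose OGTT glucose noise SD, mg/dL.
#' @param insulin_noise_frac,insulin_noise_floor insulin noise model (SD =
#'   `max(frac * value, floor)` uIU/mL).
#' @param flip_rate probability that a patient's post-operative event
#'   pattern is swapped across groups (label noise), in `[0, 0.5)`.
#' @param seed master seed.
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(n_patients, igm_fraction = 0.318,
                          SI_median = c(ngm = 0.356, igm = 0.155),
                          sigma_median = c(ngm = 3.424, igm = 1.596),
                          SI_sdlog = 0.45, sigma_sdlog = 0.35,
                          noise_sd_glucose = 5,
                          insulin_noise_frac = 0.15,
                          insulin_noise_floor = 2,
                          flip_rate = 0.1, seed = 1L) {
  b <- parameter_bounds()
  stopifnot(igm_fraction > 0, igm_fraction < 1,
            all(SI_median > b$S_I[1]), all(SI_median < b$S_I[2]),
            all(sigma_median > b$sigma[1]), all(sigma_median < b$sigma[2]),
            flip_rate >= 0, flip_rate < 0.5)
  structure(list(n_patients = as.integer(n_patients),
                 igm_fraction = igm_fraction,
                 SI_median = SI_median, sigma_median = sigma_median,
                 SI_sdlog = SI_sdlog, sigma_sdlog = sigma_sdlog,
                 noise_sd_glucose = noise_sd_glucose,
                 insulin_noise_frac = insulin_noise_frac,
                 insulin_noise_floor = insulin_noise_floor,
                 flip_rate = flip_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

# log-normal draw by median/sdlog, rejected into [lo, hi]
draw_bounded_lognormal <- function(median, sdlog, lo, hi, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    x <- stats::rlnorm(1, meanlog = log(median), sdlog = sdlog)
    if (x >= lo && x <= hi) return(x)
  }
  stop("could not draw a parameter inside the model bounds")
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate one noisy OGTT observation from the forward model
#'
#' Simulates the mechanistic model from the fasting steady state at the
#' given latent parameters and adds Gaussian measurement noise (SD 0 gives
#' the noise-free curve).  Post-noise glucose is truncated below at
#' 20 mg/dL.  Draws come from the current RNG stream unless `seed` is
#' given.
#'
#' @param sigma,SI latent parameters (within bounds).
#' @param noise_sd_glucose glucose noise SD, mg/dL.
#' @param insulin_noise_frac,insulin_noise_floor insulin noise model.
#' @param G_fast fasting glucose, mg/dL.
#' @param times OGTT sampling times.
#' @param patient_id identifier for the observation.
#' @param params fixed model constants.
#' @param seed optional seed.
#' @param with_insulin include noisy insulin values (default TRUE).
#' @return an [ogtt_observation()] with attribute `"truth"` holding the
#'   noise-free trajectory.
#' @export
generate_ogtt_observation <- function(sigma, SI, noise_sd_glucose = 5,
                                      insulin_noise_frac = 0.15,
                                      insulin_noise_floor = 2,
                                      G_fast = 90, times = c(0, 30, 60, 120),
                                      patient_id = "p1",
                                      params = model_parameters(),
                                      seed = NULL, with_insulin = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  params$S_I <- SI
  params$sigma <- sigma
  validate_model_parameters(params)
  traj <- simulate_ogtt(params, times, init_G = G_fast, method = "rk45")
  g <- traj$glucose_mgdl + stats::rnorm(length(times), 0, noise_sd_glucose)
  g <- pmax(g, 20)
  ins <- NULL
  if (with_insulin) {
    sd_i <- pmax(insulin_noise_frac * traj$insulin_uIUml, insulin_noise_floor)
    if (noise_sd_glucose == 0) sd_i <- 0  # noise-free mode
    ins <- pmax(traj$insulin_uIUml + stats::rnorm(length(times), 0, sd_i), 0)
  }
  obs <- ogtt_observation(patient_id, g, ins, times)
  attr(obs, "truth") <- traj
  obs
}

#' Generate post-operative events consistent with a latent group
#'
#' Patients in the impaired group receive one or two randomly chosen
#' triggering event patterns among the five labelling criteria; normal
#' patients receive all-normal values.  With probability `flip_rate` the
#' pattern is swapped (label noise).  The intended criteria are recorded
#' in attribute `"truth"`.
#'
#' @param group `"IGM"` or `"NGM"` (latent).
#' @param flip_rate label-noise probability in `[0, 0.5)`.
#' @param surgery_date Date of surgery.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return a [postop_events()] object with attributes `"truth"` (intended
#'   criteria) and `"effective_group"`.
#' @export
generate_events <- function(group, flip_rate = 0, surgery_date = as.Date("2015-06-01"),
                            seed = NULL) {
  stopifnot(group %in% c("IGM", "NGM"), flip_rate >= 0, flip_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  flip <- stats::runif(1) < flip_rate
  eff <- if (flip) setdiff(c("IGM", "NGM"), group) else group
  mo <- function(m) surgery_date + round(m * DAYS_PER_MONTH)
  crits <- character(0)
  # all-normal defaults (always present so the window is informative)
  hba1c <- data.frame(date = mo(c(8, 14)), value = stats::runif(2, 5.0, 5.6))
  g0 <- data.frame(date = mo(12), value = stats::runif(1, 82, 99))
  g120 <- data.frame(date = mo(12), value = stats::runif(1, 95, 139))
  meds <- data.frame(date = as.Date(character(0)), class = character(0))
  n_enc <- 4L
  enc_codes <- rep("", n_enc)
  if (eff == "IGM") {
    crits <- sample(c("hba1c", "g0", "g120", "meds", "dx_codes"),
                    size = sample(1:2, 1))
    if ("hba1c" %in% crits) hba1c$value <- stats::runif(2, 5.7, 6.4)
    if ("g0" %in% crits) g0$value <- stats::runif(1, 100, 125)
    if ("g120" %in% crits) g120$value <- stats::runif(1, 140, 199)
    if ("meds" %in% crits) {
      meds <- data.frame(date = mo(9), class = "metformin")
    }
    if ("dx_codes" %in% crits) {
      enc_codes[1:2] <- sample(c("T2DM", "ABN_GLU"), 2, replace = TRUE)
    }
  }
  encounters <- data.frame(date = mo(seq(7, 17, length.out = n_enc)),
                           codes = enc_codes)
  ev <- postop_events(hba1c = hba1c, ogtt_g0 = g0, ogtt_g120 = g120,
                      antidiabetic_meds = meds, encounters = encounters)
  attr(ev, "truth") <- crits
  attr(ev, "effective_group") <- eff
  ev
}

# group-shifted clinical lab distributions (NGM, IGM center pairs)
lab_models <- function() {
  list(
    hba1c = list(mean = c(5.4, 5.8), sd = 0.3, lo = 4),
    tsh = list(mean = c(2.3, 2.8), sd = 0.8, lo = 0.1),
    t4 = list(mean = c(8.2, 8.7), sd = 1.1, lo = 2),
    ft4 = list(mean = c(1.14, 1.16), sd = 0.12, lo = 0.4),
    t3 = list(mean = c(120, 125), sd = 25, lo = 30),
    ast = list(mean = c(19, 19), sd = 5, lo = 5),
    alt = list(mean = c(18.5, 20), sd = 6, lo = 4),
    tc = list(mean = c(164, 164), sd = 25, lo = 60),
    hdl = list(mean = c(42, 43), sd = 8, lo = 15),
    ldl = list(mean = c(95, 101), sd = 20, lo = 30),
    tg = list(mean = c(103, 95), sd = 30, lo = 25),
    c_peptide = list(mean = c(3, 3.6), sd = 1, lo = 0.3),
    bmi = list(mean = c(45.9, 48.2), sd = 6, lo = 30)
  )
}

# comorbidity prevalences by group (NGM, IGM), mirroring the direction of
# the cohort tables; carried as encounter-code fractions.
comorbidity_models <- function() {
  list(
    t2dm = c(0.08, 0.23), abnormal_glucose = c(0.13, 0.34),
    dyslipidemia = c(0.29, 0.36), hypertension = c(0.22, 0.41),
    osa = c(0.35, 0.43), liver_disease = c(0.18, 0.21),
    pcos = c(0.20, 0.35), mets = c(0.29, 0.32),
    thyroid_disease = c(0.04, 0.09), gerd = c(0.13, 0.14)
  )
}

#' Generate a synthetic patient cohort
#'
#' Draws latent group membership and per-group (S_I, sigma), simulates
#' noisy OGTT curves through the forward model, generates group-shifted
#' clinical covariates and pre-operative encounters, and post-operative
#' events that reproduce the latent group up to the configured flip rate.
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [cohort_config()].
#' @return list of `synthetic_patient` objects, each with fields
#'   `patient_id`, `group` (latent), `SI_true`, `sigma_true`,
#'   `observation`, `record`, `events`, `truth` (list: intended criteria,
#'   effective group).
#' @export
generate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  b <- parameter_bounds()
  base_params <- model_parameters()
  lm_ <- lab_models()
  cm <- comorbidity_models()
  surgery_date <- as.Date("2015-06-01")
  out <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    gi <- if (stats::runif(1) < cfg$igm_fraction) 2L else 1L
    group <- c("NGM", "IGM")[gi]
    key <- c("ngm", "igm")[gi]
    SI <- draw_bounded_lognormal(cfg$SI_median[[key]], cfg$SI_sdlog,
                                 b$S_I[1], b$S_I[2])
    sigma <- draw_bounded_lognormal(cfg$sigma_median[[key]], cfg$sigma_sdlog,
                                    b$sigma[1], b$sigma[2])
    G_fast <- rnorm_trunc(1, c(87, 90)[gi], 5, 70, 120)
    pid <- sprintf("P%04d", i)
    obs <- generate_ogtt_observation(
      sigma, SI, cfg$noise_sd_glucose, cfg$insulin_noise_frac,
      cfg$insulin_noise_floor, G_fast = G_fast, patient_id = pid,
      params = base_params)

    labs <- data.frame(
      analyte = c("ogtt_g_0", "ogtt_g_30", "ogtt_g_60", "ogtt_g_120",
                  "ogtt_i_0", "ogtt_i_30", "ogtt_i_60", "ogtt_i_120"),
      date = surgery_date - 60,
      value = c(obs$glucose, obs$insulin)
    )
    for (nm in names(lm_)) {
      m <- lm_[[nm]]
      labs <- rbind(labs, data.frame(
        analyte = nm, date = surgery_date - 45,
        value = rnorm_trunc(1, m$mean[gi], m$sd, m$lo)))
    }
    n_enc <- 4L + stats::rpois(1, 4)
    enc_codes <- rep("", n_enc)
    for (nm in names(cm)) {
      if (stats::runif(1) < cm[[nm]][gi]) {
        carry <- seq_len(max(ceiling(0.4 * n_enc), 1))
        code <- toupper(comorbidity_code_sets()[[nm]][1])
        enc_codes[carry] <- ifelse(enc_codes[carry] == "", code,
                                   paste(enc_codes[carry], code, sep = ";"))
      }
    }
    encounters <- data.frame(
      date = surgery_date - sort(round(stats::runif(n_enc, 30, 5 * 365))),
      codes = enc_codes)
    rec <- patient_record(
      patient_id = pid,
      age_years = rnorm_trunc(1, 16.9, 1.5, 13, 21),
      sex = sample(c("F", "M"), 1, prob = c(0.7, 0.3)),
      race = sample(c("white", "black", "other", "unknown"), 1,
                    prob = c(0.55, 0.21, 0.05, 0.19)),
      ethnicity = sample(c("hispanic", "non_hispanic", "unknown"), 1,
                         prob = c(0.45, 0.48, 0.07)),
      surgery_type = sample(c("VSG", "AGB"), 1, prob = c(0.5, 0.5)),
      surgery_date = surgery_date, labs = labs, encounters = encounters)
    ev <- generate_events(group, cfg$flip_rate, surgery_date)
    out[[i]] <- structure(
      list(patient_id = pid, group = group, SI_true = SI, sigma_true = sigma,
           observation = obs, record = rec, events = ev,
           truth = list(criteria = attr(ev, "truth"),
                        effective_group = attr(ev, "effective_group"))),
      class = "synthetic_patient")
  }
  out
}

#' Extract the pieces of a synthetic cohort
#'
#' @param cohort list from [generate_cohort()].
#' @return `cohort_observations`: list of [ogtt_observation()];
#'   `cohort_records`: list of [patient_record()]; `cohort_labels`: named
#'   logical vector of [label_igm()] outcomes; `cohort_truth`: data.frame
#'   of latent parameters and groups.
#' @export
cohort_observations <- function(cohort) lapply(cohort, `[[`, "observation")

#' @rdname cohort_observations
#' @export
cohort_records <- function(cohort) lapply(cohort, `[[`, "record")

#' @rdname cohort_observations
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort, function(p) {
    label_igm(p$events, p$record$surgery_date)$igm
  }, TRUE, USE.NAMES = FALSE) |>
    stats::setNames(vapply(cohort, `[[`, "", "patient_id"))
}

#' @rdname cohort_observations
#' @export
cohort_truth <- function(cohort) {
  data.frame(
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    group = vapply(cohort, `[[`, "", "group"),
    effective_group = vapply(cohort, function(p) p$truth$effective_group, ""),
    SI_true = vapply(cohort, `[[`, 0, "SI_true"),
    sigma_true = vapply(cohort, `[[`, 0, "sigma_true")
  )
}

#' Standardized feature matrix from posterior summaries alone
#'
#' Box-Cox-standardizes the six posterior-summary columns into a model
#' feature matrix (the "data-assimilation only" variant).
#'
#' @param summaries data.frame from [fit_cohort()].
#' @return numeric matrix with rows named by patient id.
#' @export
da_feature_matrix <- function(summaries) {
  cols <- c("mean_SI", "sd_SI", "mean_sigma", "sd_sigma",
            "mean_product", "sd_product")
  x <- sapply(cols, function(j) boxcox_standardize(summaries[[j]])$values)
  rownames(x) <- as.character(summaries$patient_id)
  x
}

#' Run the full pipeline on a synthetic cohort
#'
#' generate -> per-patient MCMC -> outcome labelling -> feature matrix ->
#' bootstrap out-of-bag evaluation.  Deterministic given the seeds inside
#' the two configs.
#'
#' @param cohort_cfg a [cohort_config()].
#' @param infer_cfg an [inference_config()] (desk-scale chain lengths are
#'   fine here).
#' @param hyperparams model configuration for [train_logreg()].
#' @param n_boot bootstrap replicates for the evaluation.
#' @param features `"da_only"` (six posterior summaries) or
#'   `"clinical_da"` (clinical matrix plus summaries).
#' @return list with `report` (`evaluation_report`), `summaries`, `labels`,
#'   `truth`, `cohort`.
#' @export
run_pipeline <- function(cohort_cfg, infer_cfg,
                         hyperparams = list(penalty = "l2", lambda = 0.01,
                                            maxit = 1e4),
                         n_boot = 200, features = c("da_only", "clinical_da")) {
  features <- match.arg(features)
  cohort <- generate_cohort(cohort_cfg)
  summaries <- fit_cohort(cohort_observations(cohort), infer_cfg)
  labels <- cohort_labels(cohort)
  keep <- !is.na(labels)
  summaries <- summaries[keep, , drop = FALSE]
  labels <- labels[keep]
  x <- if (features == "da_only") {
    da_feature_matrix(summaries)
  } else {
    fm <- build_feature_matrix(cohort_records(cohort)[keep],
                               da_summaries = summaries,
                               seed = cohort_cfg$seed)
    fm$features
  }
  report <- bootstrap_oob_evaluate(x, as.integer(labels), hyperparams,
                                   n_boot = n_boot, seed = infer_cfg$seed,
                                   variant = paste0("synthetic_", features))
  list(report = report, summaries = summaries, labels = labels,
       truth = cohort_truth(cohort), cohort = cohort)
}
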