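#' Homeostatic model assessment of insulin resistance (mass units)
#'
#' `HOMA-IR = G0 * I0 / 405` with fasting glucose in mg/dL and fasting
#' insulin in uIU/mL.
#'
#' @param G0 fasting glucose, mg/dL (`> 0`).
#' @param I0 fasting insulin, uIU/mL (`>= 0`).
#' @return the index (vectorised).
#' @export
#' @examples
#' homa_ir(90, 10)  # 2.2222...
homa_ir <- function(G0, I0) {
  if (any(G0 <= 0)) stop("fasting glucose must be positive")
  if (any(I0 < 0)) stop("fasting insulin must be non-negative")
  G0 * I0 / 405
}

#' Flag IQR outliers in a continuous column
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.  Values are only
#' flagged, never removed.
#'
#' @param values numeric vector (NAs ignored; at least 4 non-missing).
#' @return logical vector (NA where the value is missing).
#' @export
flag_outliers <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4) stop("need at least 4 non-missing values")
  q <- stats::quantile(values[ok], c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  out <- values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
  out
}

# Box-Cox transform of a positive vector at a given lambda.
boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' Box-Cox transform and standardize a positive column
#'
#' Chooses the Box-Cox exponent by profile maximum likelihood, transforms,
#' and standardizes to mean 0 / SD 1.  The returned metadata makes the
#' mapping invertible (see [inverse_boxcox()]).
#'
#' @param column positive numeric vector (NAs allowed and preserved).
#' @param lambda_range search interval for the exponent.
#' @return list with `values` (transformed, standardized), `lambda`,
#'   `location` (pre-standardization mean), `scale` (pre-standardization SD).
#' @export
boxcox_standardize <- function(column, lambda_range = c(-3, 3)) {
  ok <- !is.na(column)
  x <- column[ok]
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values")
  if (stats::sd(x) == 0) {
    # constant column: identity exponent, center only
    out <- rep(NA_real_, length(column))
    out[ok] <- 0
    return(list(values = out, lambda = 1,
                location = boxcox_transform(x[1], 1), scale = 1))
  }
  n <- length(x)
  slx <- sum(log(x))
  prof <- function(lam) {
    y <- boxcox_transform(x, lam)
    -n / 2 * log(mean((y - mean(y))^2)) + (lam - 1) * slx
  }
  lambda <- stats::optimize(prof, lambda_range, maximum = TRUE)$maximum
  y <- boxcox_transform(x, lambda)
  loc <- mean(y)
  sc <- stats::sd(y)
  if (sc == 0) sc <- 1  # constant column: center only
  out <- rep(NA_real_, length(column))
  out[ok] <- (y - loc) / sc
  list(values = out, lambda = lambda, location = loc, scale = sc)
}

#' Invert a Box-Cox standardization
#'
#' @param z standardized transformed values.
#' @param lambda,location,scale metadata from [boxcox_standardize()].
#' @return values on the original scale.
#' @export
inverse_boxcox <- function(z, lambda, location, scale) {
  y <- z * scale + location
  if (abs(lambda) < 1e-8) exp(y) else (lambda * y + 1)^(1 / lambda)
}

#' Iterative imputation of missing entries
#'
#' Round-robin conditional imputation: each incomplete column is regressed
#' on its five most-correlated (absolute Pearson, complete pairs) columns
#' and missing entries are replaced by draws from the predictive
#' distribution (fitted value plus residual-scale Gaussian noise), not
#' point estimates.  Observed entries are never modified.  Deterministic
#' given `seed`.
#'
#' @param X numeric matrix with column names; every column at most 25%
#'   missing, none fully missing.
#' @param n_neighbors number of predictor columns (default 5).
#' @param seed integer seed.
#' @param max_rounds,tol stopping rule: `max_rounds` sweeps or relative
#'   change of imputed values below `tol`.
#' @return the completed matrix.
#' @export
impute_missing <- function(X, n_neighbors = 5, seed = 1L,
                           max_rounds = 10, tol = 1e-3) {
  miss <- is.na(X)
  if (!any(miss)) return(X)
  frac <- colMeans(miss)
  if (any(frac == 1)) stop("fully missing column(s): ",
                           paste(colnames(X)[frac == 1], collapse = ", "))
  if (any(frac > 0.25)) stop("column(s) above 25% missingness should have been dropped")
  set.seed(seed)
  filled <- X
  for (j in seq_len(ncol(X))) {
    if (any(miss[, j])) filled[miss[, j], j] <- mean(X[, j], na.rm = TRUE)
  }
  co <- suppressWarnings(abs(stats::cor(X, use = "pairwise.complete.obs")))
  diag(co) <- 0
  co[is.na(co)] <- 0
  targets <- which(colSums(miss) > 0)
  for (round in seq_len(max_rounds)) {
    prev <- filled[miss]
    for (j in targets) {
      nb <- order(co[, j], decreasing = TRUE)[seq_len(min(n_neighbors, ncol(X) - 1))]
      obs <- !miss[, j]
      fit <- stats::lm.fit(cbind(1, filled[obs, nb, drop = FALSE]), filled[obs, j])
      sigma <- sqrt(sum(fit$residuals^2) / max(1, sum(obs) - length(nb) - 1))
      pred <- cbind(1, filled[miss[, j], nb, drop = FALSE]) %*% fit$coefficients
      filled[miss[, j], j] <- pred + stats::rnorm(sum(miss[, j]), 0, sigma)
    }
    delta <- sqrt(mean((filled[miss] - prev)^2)) /
      max(sqrt(mean(prev^2)), 1e-12)
    if (delta < tol) break
  }
  stopifnot(identical(filled[!miss], X[!miss]))
  filled
}

#' Encounter-fraction comorbidity coding
#'
#' A comorbidity flag is TRUE iff at least `threshold` (default 25%) of the
#' encounters inside the time window carry any diagnosis code from
#' `code_set`.  A window with zero encounters yields FALSE.
#'
#' @param encounters data.frame with columns `date` (Date) and `codes`
#'   (`";"`-separated code string per encounter).
#' @param code_set character vector of qualifying codes.
#' @param window `c(start, end)` Dates, inclusive.
#' @param threshold fraction of encounters required (default 0.25).
#' @return logical flag.
#' @export
encode_comorbidity <- function(encounters, code_set, window, threshold = 0.25) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (is.null(encounters) || nrow(encounters) == 0) return(FALSE)
  d <- as.Date(encounters$date)
  inw <- d >= window[1] & d <= window[2]
  if (!any(inw)) return(FALSE)
  hit <- vapply(strsplit(encounters$codes[inw], ";", fixed = TRUE),
                function(cs) any(cs %in% code_set), TRUE)
  mean(hit) >= threshold
}

#' Construct a clinical patient record
#'
#' @param patient_id identifier.
#' @param age_years age at surgery.
#' @param sex,race,ethnicity,surgery_type categorical values.
#' @param surgery_date Date of surgery.
#' @param labs data.frame `analyte, date, value` (long format, one row per
#'   lab result).
#' @param encounters data.frame `date, codes` (see [encode_comorbidity()]).
#' @param medications data.frame `class, date`.
#' @return a `patient_record` object.
#' @export
patient_record <- function(patient_id, age_years, sex, race, ethnicity,
                           surgery_type, surgery_date,
                           labs = data.frame(analyte = character(0),
                                             date = as.Date(character(0)),
                                             value = numeric(0)),
                           encounters = data.frame(date = as.Date(character(0)),
                                                   codes = character(0)),
                           medications = data.frame(class = character(0),
                                                    date = as.Date(character(0)))) {
  structure(list(patient_id = patient_id, age_years = age_years, sex = sex,
                 race = race, ethnicity = ethnicity,
                 surgery_type = surgery_type,
                 surgery_date = as.Date(surgery_date), labs = labs,
                 encounters = encounters, medications = medications),
            class = "patient_record")
}

# Closest lab value at or before the surgery date (latest such lab);
# NA when the analyte is absent.
closest_preop_lab <- function(record, analyte) {
  li <- record$labs[record$labs$analyte == analyte, ]
  li <- li[as.Date(li$date) <= record$surgery_date, ]
  if (nrow(li) == 0) return(NA_real_)
  li$value[which.max(as.Date(li$date))]
}

#' Comorbidity code sets used by the default feature specification
#'
#' Synthetic symbolic code sets (not a real diagnosis vocabulary) for the
#' comorbidities carried as binary features, plus the outcome-relevant
#' T2DM / abnormal-glucose sets.
#'
#' @return named list of character vectors.
#' @export
comorbidity_code_sets <- function() {
  list(
    t2dm = "T2DM", abnormal_glucose = "ABN_GLU",
    dyslipidemia = "DYSLIP", hypertension = "HTN", osa = "OSA",
    liver_disease = "LIVER", pcos = "PCOS", mets = "METS",
    thyroid_disease = "THYROID", gerd = "GERD"
  )
}

#' Default feature specification
#'
#' Names the continuous analytes, categorical variables and comorbidity
#' flags carried into the model feature matrix.
#'
#' @param include_insulin keep the OGTT insulin columns (and HOMA-IR's
#'   insulin input) among the continuous features.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(include_insulin = TRUE) {
  cont <- c("hba1c", "ogtt_g_0", "ogtt_g_30", "ogtt_g_60", "ogtt_g_120",
            "tsh", "t4", "ft4", "t3", "ast", "alt", "tc", "hdl", "ldl",
            "tg", "c_peptide", "bmi")
  if (include_insulin) {
    cont <- c(cont, "ogtt_i_0", "ogtt_i_30", "ogtt_i_60", "ogtt_i_120")
  }
  structure(list(
    continuous = cont,
    include_insulin = include_insulin,
    categoricals = c("sex", "race", "ethnicity", "surgery_type"),
    comorbidities = comorbidity_code_sets(),
    preop_code_window_years = 5,
    missing_cutoff = 0.25
  ), class = "feature_spec")
}

#' Build the standardized model feature matrix
#'
#' Selects the closest pre-surgery lab per analyte, computes
#' encounter-fraction comorbidity flags over the 5-year pre-operative
#' window, drops columns above 25% missingness, Box-Cox-standardizes
#' continuous columns, one-hot encodes categoricals (most frequent level
#' dropped), imputes remaining missing entries, and optionally appends
#' either the six posterior-summary features or HOMA-IR --- never both.
#'
#' @param records list of [patient_record()] with unique ids.
#' @param spec a [feature_spec()].
#' @param da_summaries optional data.frame from [fit_cohort()] (keyed by
#'   `patient_id`) whose six summary columns are appended as features.
#' @param include_homa append HOMA-IR (mutually exclusive with
#'   `da_summaries`).
#' @param age_shift constant added to age before Box-Cox (ages are already
#'   positive; kept for generality, default 0).
#' @param seed seed for the imputation draws.
#' @return a `feature_matrix`: list with `features` (numeric matrix, rows
#'   named by patient id), `mask` (original missingness), `transforms`
#'   (per-column Box-Cox metadata), `outlier_flags`, `variant`.
#' @export
build_feature_matrix <- function(records, spec = feature_spec(),
                                 da_summaries = NULL, include_homa = FALSE,
                                 age_shift = 0, seed = 1L) {
  ids <- vapply(records, function(r) as.character(r$patient_id), "")
  if (anyDuplicated(ids)) stop("duplicate patient ids")
  if (include_homa && !is.null(da_summaries)) {
    stop("HOMA-IR and data-assimilation summary features are mutually exclusive")
  }
  n <- length(records)

  cont <- sapply(spec$continuous, function(a) {
    vapply(records, closest_preop_lab, 0, analyte = a)
  })
  cont <- matrix(cont, nrow = n, dimnames = list(ids, spec$continuous))
  age <- vapply(records, function(r) r$age_years, 0) + age_shift
  cont <- cbind(cont, age_years = age)
  if (include_homa) {
    g0 <- vapply(records, closest_preop_lab, 0, analyte = "ogtt_g_0")
    i0 <- vapply(records, closest_preop_lab, 0, analyte = "ogtt_i_0")
    cont <- cbind(cont, homa_ir = ifelse(is.na(g0) | is.na(i0), NA,
                                         homa_ir(pmax(g0, 1e-9), pmax(i0, 0))))
  }
  if (!is.null(da_summaries)) {
    da_cols <- c("mean_SI", "sd_SI", "mean_sigma", "sd_sigma",
                 "mean_product", "sd_product")
    m <- match(ids, as.character(da_summaries$patient_id))
    if (any(is.na(m))) stop("da_summaries missing patients: ",
                            paste(ids[is.na(m)], collapse = ", "))
    cont <- cbind(cont, as.matrix(da_summaries[m, da_cols]))
  }

  # drop columns above the missingness cutoff
  keep <- colMeans(is.na(cont)) <= spec$missing_cutoff
  cont <- cont[, keep, drop = FALSE]
  mask <- is.na(cont)

  outlier_flags <- lapply(as.data.frame(cont), function(x) {
    if (sum(!is.na(x)) >= 4) flag_outliers(x) else rep(NA, length(x))
  })

  transforms <- list()
  for (j in colnames(cont)) {
    bc <- boxcox_standardize(cont[, j])
    cont[, j] <- bc$values
    transforms[[j]] <- bc[c("lambda", "location", "scale")]
  }
  if (any(mask)) cont <- impute_missing(cont, seed = seed)

  # comorbidity flags over the 5-year pre-operative window
  flags <- sapply(names(spec$comorbidities), function(nm) {
    vapply(records, function(r) {
      win <- c(r$surgery_date - round(spec$preop_code_window_years * 365.25),
               r$surgery_date)
      as.numeric(encode_comorbidity(r$encounters, spec$comorbidities[[nm]], win))
    }, 0)
  })
  flags <- matrix(flags, nrow = n,
                  dimnames = list(ids, paste0("com_", names(spec$comorbidities))))

  # one-hot categoricals, most frequent level dropped
  onehot <- NULL
  for (v in spec$categoricals) {
    vals <- vapply(records, function(r) as.character(r[[v]]), "")
    tab <- sort(table(vals), decreasing = TRUE)
    lev <- names(tab)[-1]
    if (length(lev)) {
      cols <- sapply(lev, function(l) as.numeric(vals == l))
      cols <- matrix(cols, nrow = n,
                     dimnames = list(ids, paste0(v, "_", lev)))
      onehot <- cbind(onehot, cols)
    }
  }

  features <- cbind(cont, flags, onehot)
  stopifnot(!anyNA(features))
  structure(list(features = features, mask = mask, transforms = transforms,
                 outlier_flags = outlier_flags,
                 variant = if (!is.null(da_summaries)) "da"
                           else if (include_homa) "homa_ir"
                           else if (spec$include_insulin) "clinical"
                           else "clinical_no_insulin"),
            class = "feature_matrix")
}

#' Write a feature matrix and its transform metadata
#'
#' Writes the matrix as delimited text plus a JSON sidecar of per-column
#' Box-Cox metadata.
#'
#' @param fm a `feature_matrix` from [build_feature_matrix()].
#' @param file CSV output path; the sidecar is `paste0(file, ".json")`.
#' @export
write_feature_matrix <- function(fm, file) {
  df <- data.frame(patient_id = rownames(fm$features), fm$features,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(fm$transforms, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
}
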