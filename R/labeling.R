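#' Post-operative event record for outcome labelling
#'
#' @param hba1c data.frame `date, value` (HbA1c, percent).
#' @param ogtt_g0,ogtt_g120 data.frames `date, value` (mg/dL).
#' @param antidiabetic_meds data.frame `date, class` (drug class, e.g.
#'   `"metformin"`, `"glp1a"`, `"insulin"`, `"other"`).
#' @param encounters data.frame `date, codes` (`";"`-separated codes).
#' @return a `postop_events` object.
#' @export
postop_events <- function(hba1c = empty_events(), ogtt_g0 = empty_events(),
                          ogtt_g120 = empty_events(),
                          antidiabetic_meds = data.frame(date = as.Date(character(0)),
                                                         class = character(0)),
                          encounters = data.frame(date = as.Date(character(0)),
                                                  codes = character(0))) {
  structure(list(hba1c = hba1c, ogtt_g0 = ogtt_g0, ogtt_g120 = ogtt_g120,
                 antidiabetic_meds = antidiabetic_meds,
                 encounters = encounters),
            class = "postop_events")
}

empty_events <- function() {
  data.frame(date = as.Date(character(0)), value = numeric(0))
}

# One month of follow-up time, days (30.44-day months for date arithmetic).
DAYS_PER_MONTH <- 30.44

# value of the latest in-window lab, or NA when none
latest_in_window <- function(events, window) {
  if (is.null(events) || nrow(events) == 0) return(NA_real_)
  d <- as.Date(events$date)
  inw <- d >= window[1] & d <= window[2]
  if (!any(inw)) return(NA_real_)
  events$value[inw][which.max(d[inw])]
}

# Shared criterion engine: applies the five impaired-glucose-metabolism
# criteria to events restricted to a window.  Returns the fired criteria.
igm_criteria <- function(events, window) {
  fired <- character(0)

  a1c <- events$hba1c
  if (!is.null(a1c) && nrow(a1c) > 0) {
    d <- as.Date(a1c$date)
    inw <- d >= window[1] & d <= window[2]
    if (sum(a1c$value[inw] >= 5.7) >= 2) fired <- c(fired, "hba1c")
  }
  g0 <- latest_in_window(events$ogtt_g0, window)
  if (!is.na(g0) && g0 >= 100) fired <- c(fired, "g0")
  g120 <- latest_in_window(events$ogtt_g120, window)
  if (!is.na(g120) && g120 >= 140) fired <- c(fired, "g120")
  meds <- events$antidiabetic_meds
  if (!is.null(meds) && nrow(meds) > 0) {
    d <- as.Date(meds$date)
    if (any(d >= window[1] & d <= window[2])) fired <- c(fired, "meds")
  }
  codes <- c("T2DM", "ABN_GLU")
  if (encode_comorbidity(events$encounters, codes, window)) {
    fired <- c(fired, "dx_codes")
  }
  fired
}

# Whether any labelling information exists inside the window.
has_in_window_info <- function(events, window) {
  dated <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(FALSE)
    d <- as.Date(df$date)
    any(d >= window[1] & d <= window[2])
  }
  dated(events$hba1c) || dated(events$ogtt_g0) || dated(events$ogtt_g120) ||
    dated(events$antidiabetic_meds) || dated(events$encounters)
}

#' Label 12-month post-operative impaired glucose metabolism
#'
#' Restricts all events to the 6--18-month post-operative window (both
#' ends inclusive, 30.44-day months) and fires any of: (a) at least two
#' HbA1c values >= 5.7%; (b) latest in-window fasting OGTT glucose
#' >= 100 mg/dL; (c) latest in-window 120-min OGTT glucose >= 140 mg/dL;
#' (d) any anti-diabetic drug use (metformin and GLP-1 agonists included);
#' (e) T2DM or abnormal-glucose diagnosis codes in at least 25% of
#' in-window encounters.  For repeated labs the latest value is used.
#'
#' @param events a [postop_events()] record.
#' @param surgery_date Date of surgery.
#' @return an `outcome_label`: list with `igm` (logical, NA when no
#'   in-window information exists), `triggered_criteria` (subset of
#'   `hba1c, g0, g120, meds, dx_codes`), `window` (Dates).
#' @export
label_igm <- function(events, surgery_date) {
  surgery_date <- as.Date(surgery_date)
  window <- surgery_date + round(c(6, 18) * DAYS_PER_MONTH)
  if (!has_in_window_info(events, window)) {
    return(structure(list(igm = NA, triggered_criteria = character(0),
                          window = window), class = "outcome_label"))
  }
  fired <- igm_criteria(events, window)
  structure(list(igm = length(fired) > 0, triggered_criteria = fired,
                 window = window),
            class = "outcome_label")
}

#' Pre-operative impaired-glucose-metabolism flag (reporting only)
#'
#' Applies the same five criteria to the pre-operative window (diagnosis
#' codes over 5 pre-operative years; labs/medications likewise).  The flag
#' is descriptive and structurally excluded from every model feature
#' matrix.
#'
#' @param record a [patient_record()] (pre-operative labs are read from
#'   `record$labs`: analytes `hba1c`, `ogtt_g_0`, `ogtt_g_120`).
#' @param code_window_years pre-operative code window length (default 5).
#' @return logical flag.
#' @export
label_preop_igm <- function(record, code_window_years = 5) {
  sdate <- record$surgery_date
  window <- c(sdate - round(code_window_years * 365.25), sdate)
  lab_events <- function(analyte) {
    li <- record$labs[record$labs$analyte == analyte, ]
    data.frame(date = as.Date(li$date), value = li$value)
  }
  ev <- postop_events(
    hba1c = lab_events("hba1c"),
    ogtt_g0 = lab_events("ogtt_g_0"),
    ogtt_g120 = lab_events("ogtt_g_120"),
    antidiabetic_meds = record$medications,
    encounters = record$encounters
  )
  length(igm_criteria(ev, window)) > 0
}

#' Prevalence of an IGM flag, as a printed percentage
#'
#' @param flags logical vector (NAs dropped).
#' @param digits decimals in the reported percentage (default 1).
#' @return percentage, e.g. `57.4`.
#' @export
igm_prevalence <- function(flags, digits = 1) {
  round(100 * mean(flags, na.rm = TRUE), digits)
}

#' Write outcome labels to delimited text
#'
#' @param labels list of `outcome_label` objects keyed by patient id (named
#'   list), optionally with a parallel `preop` logical vector.
#' @param file output CSV path.
#' @param preop optional named logical vector of pre-operative flags.
#' @export
write_labels <- function(labels, file, preop = NULL) {
  df <- data.frame(
    patient_id = names(labels),
    igm = vapply(labels, function(l) l$igm, TRUE),
    triggered_criteria = vapply(labels, function(l)
      paste(l$triggered_criteria, collapse = ";"), ""),
    preop_igm = if (is.null(preop)) NA else preop[names(labels)]
  )
  utils::write.csv(df, file, row.names = FALSE)
}
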