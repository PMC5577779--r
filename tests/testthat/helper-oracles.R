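# Independent brute-force oracles: plain loops over event rows, written
# directly from the outcome definitions, against which the vectorised
# implementations are checked.

SRC_ORDER <- c("visit", "lab", "pharmacy")

make_patient <- function(patient_id = "P1",
                         transfer_out_date = as.Date("2010-06-01"),
                         origin_facility = "ORIGIN",
                         origin_level = "tertiary",
                         age_at_transfer = 12,
                         age_at_enrolment = 5,
                         vl_at_transfer = NA_real_,
                         cd4_at_transfer = NA_real_) {
  tibble::tibble(
    patient_id = patient_id,
    sex = "female",
    enrolment_date = transfer_out_date - 2000,
    art_start_date = transfer_out_date - 1900,
    age_at_enrolment = age_at_enrolment,
    age_at_art_start = age_at_enrolment + 0.2,
    age_at_transfer = age_at_transfer,
    transfer_out_date = transfer_out_date,
    origin_facility = origin_facility,
    origin_level = origin_level,
    cd4_at_transfer = cd4_at_transfer,
    vl_at_transfer = vl_at_transfer,
    cd4_at_art_start = NA_real_,
    cd4pct_at_art_start = NA_real_
  )
}

make_events <- function(patient_id, facility, date, source,
                        analyte = NULL, value = NULL) {
  n <- length(date)
  if (is.null(analyte)) analyte <- ifelse(source == "lab", "hiv_rna", "none")
  if (is.null(value)) value <- ifelse(source == "lab", 100, NA_real_)
  tibble::tibble(
    patient_id = rep_len(patient_id, n),
    facility = rep_len(facility, n),
    date = date,
    source = rep_len(source, n),
    analyte = rep_len(analyte, n),
    value = as.numeric(rep_len(value, n))
  )
}

# Random small event set around one patient's transfer date.
random_event_set <- function(patient, n_events = NULL) {
  if (is.null(n_events)) n_events <- sample(0:20, 1)
  if (n_events == 0) {
    return(make_events(patient$patient_id, character(0),
                       as.Date(character(0)), character(0),
                       character(0), numeric(0)))
  }
  source <- sample(SRC_ORDER, n_events, replace = TRUE)
  analyte <- ifelse(source == "lab",
                    sample(c("hiv_rna", "cd4"), n_events, replace = TRUE),
                    "none")
  make_events(
    patient$patient_id,
    facility = sample(c(patient$origin_facility, "FAC-X", "FAC-Y"),
                      n_events, replace = TRUE),
    date = patient$transfer_out_date + sample(-300:1500, n_events,
                                              replace = TRUE),
    source = source,
    analyte = analyte,
    value = ifelse(source == "lab", sample(10:900, n_events, replace = TRUE),
                   NA_real_)
  )
}

brute_classify <- function(patient, events, config) {
  best <- NULL
  for (i in seq_len(nrow(events))) {
    e <- as.list(events[i, ])
    if (!e$source %in% config$source_subset) next
    after <- if (config$strict_after_transfer) {
      e$date > patient$transfer_out_date
    } else {
      e$date >= patient$transfer_out_date
    }
    if (!after || e$facility == patient$origin_facility) next
    if (is.null(best)) {
      best <- e
    } else {
      eb <- c(as.numeric(e$date), match(e$source, SRC_ORDER))
      bb <- c(as.numeric(best$date), match(best$source, SRC_ORDER))
      if (eb[1] < bb[1] ||
          (eb[1] == bb[1] && eb[2] < bb[2]) ||
          (eb[1] == bb[1] && eb[2] == bb[2] &&
             e$facility < best$facility)) {
        best <- e
      }
    }
  }
  if (is.null(best)) {
    return(list(success = FALSE))
  }
  last <- NULL
  for (i in seq_len(nrow(events))) {
    e <- as.list(events[i, ])
    if (!e$source %in% config$source_subset) next
    if (e$facility == patient$origin_facility &&
        e$date <= patient$transfer_out_date &&
        (is.null(last) || e$date > last)) {
      last <- e$date
    }
  }
  anchor <- if (is.null(last)) patient$transfer_out_date else last
  list(
    success = TRUE,
    success_date = best$date,
    linkage_facility = best$facility,
    linkage_source = best$source,
    delay_from_transfer_days =
      as.integer(best$date - patient$transfer_out_date),
    delay_from_last_contact_days = as.integer(best$date - anchor),
    within_18_months =
      as.integer(best$date - patient$transfer_out_date) <=
        config$months18_days
  )
}

brute_retained <- function(patient, success_date, events, year, config) {
  target <- success_date + year * config$year_days
  lo <- target - config$window_halfwidth_days
  hi <- target + config$window_halfwidth_days
  hit <- FALSE
  for (i in seq_len(nrow(events))) {
    e <- as.list(events[i, ])
    if (e$source != "visit") next
    if (!config$retention_counts_origin &&
        e$facility == patient$origin_facility) next
    if (e$date >= lo && e$date <= hi) hit <- TRUE
  }
  hit
}

brute_select_lab <- function(success_date, events, analyte, year, config) {
  target <- success_date + year * config$year_days
  best <- NULL
  for (i in seq_len(nrow(events))) {
    e <- as.list(events[i, ])
    if (e$source != "lab" || e$analyte != analyte) next
    dist <- abs(as.integer(e$date - target))
    if (dist > config$window_halfwidth_days) next
    if (is.null(best) || dist < best$dist ||
        (dist == best$dist && e$date < best$date)) {
      best <- list(date = e$date, value = e$value, dist = dist)
    }
  }
  best
}
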