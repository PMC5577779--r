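#' Classify successful transfer for every patient
#'
#' A patient transfers successfully when any record (visit, laboratory test
#' or pharmacy dispensing) exists at a facility other than the origin
#' facility after the transfer-out date — strictly after by default, since a
#' same-day record elsewhere is plausibly a pre-transfer administrative
#' contact (`strict_after_transfer` toggles this). The linkage event is the
#' earliest qualifying record; ties on date break by source priority
#' visit < lab < pharmacy, then facility lexicographically.
#'
#' Two delay measures are reported for successes: days from the transfer-out
#' date to the linkage event, and days from the last contact at the origin
#' facility on or before transfer-out (falling back to the transfer-out date
#' when the active source subset captured no such contact). Patients linking
#' within `months18_days` are additionally flagged. Only events whose source
#' lies in `config$source_subset` are considered, which is what the
#' source-sensitivity analysis varies.
#'
#' @param patients Cohort tibble (see [read_cohort()]).
#' @param events Event tibble with canonical identifiers
#'   (see [resolve_duplicates()]).
#' @param config An [analysis_config()].
#' @return A tibble with one row per patient: `patient_id`, `success`,
#'   `success_date`, `linkage_facility`, `linkage_source`,
#'   `delay_from_transfer_days`, `delay_from_last_contact_days`,
#'   `within_18_months`. Delay and linkage fields are `NA` for
#'   unsuccessful patients.
#' @export
classify_transfers <- function(patients, events, config = analysis_config()) {
  ev <- events |>
    dplyr::filter(.data$source %in% config$source_subset) |>
    dplyr::inner_join(
      dplyr::select(patients, "patient_id", "origin_facility",
                    "transfer_out_date"),
      by = "patient_id"
    )
  after <- if (config$strict_after_transfer) {
    ev$date > ev$transfer_out_date
  } else {
    ev$date >= ev$transfer_out_date
  }
  link <- ev[after & ev$facility != ev$origin_facility, , drop = FALSE] |>
    dplyr::mutate(src_rank = match(.data$source, SOURCES)) |>
    dplyr::arrange(.data$patient_id, .data$date, .data$src_rank,
                   .data$facility) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE)
  origin_ev <- ev |>
    dplyr::filter(.data$facility == .data$origin_facility,
                  .data$date <= .data$transfer_out_date)
  last_contact <- if (nrow(origin_ev) == 0) {
    tibble::tibble(patient_id = character(),
                   last_origin_contact = as.Date(character()))
  } else {
    origin_ev |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(last_origin_contact = max(.data$date),
                       .groups = "drop")
  }

  patients |>
    dplyr::select("patient_id", "transfer_out_date") |>
    dplyr::left_join(
      dplyr::select(link, "patient_id", success_date = "date",
                    linkage_facility = "facility", linkage_source = "source"),
      by = "patient_id"
    ) |>
    dplyr::left_join(last_contact, by = "patient_id") |>
    dplyr::mutate(
      success = !is.na(.data$success_date),
      anchor = dplyr::coalesce(.data$last_origin_contact,
                               .data$transfer_out_date),
      delay_from_transfer_days = dplyr::if_else(
        .data$success,
        as.integer(.data$success_date - .data$transfer_out_date),
        NA_integer_),
      delay_from_last_contact_days = dplyr::if_else(
        .data$success,
        as.integer(.data$success_date - .data$anchor),
        NA_integer_),
      within_18_months = dplyr::if_else(
        .data$success,
        .data$delay_from_transfer_days <= config$months18_days,
        NA)
    ) |>
    dplyr::select("patient_id", "success", "success_date",
                  "linkage_facility", "linkage_source",
                  "delay_from_transfer_days", "delay_from_last_contact_days",
                  "within_18_months")
}

#' @rdname classify_transfers
#' @param patient A single-row cohort tibble.
#' @return `classify_transfer()` returns the single outcome row.
#' @export
classify_transfer <- function(patient, events, config = analysis_config()) {
  stopifnot(nrow(patient) == 1)
  classify_transfers(patient, events, config)
}

#' Windowed retention and laboratory assessment at 1-3 years
#'
#' For each successfully transferred patient and each requested year after
#' successful transfer, determines eligibility (at least `year + 0.5` years
#' of potential follow-up between the successful-transfer date and database
#' closure, at 365.25 days/year), retention (at least one visit within the
#' closed window of `window_halfwidth_days` either side of the yearly time
#' point; by default visits back at the origin facility do not count), and
#' the HIV-RNA and CD4 measurements closest to the time point within the same
#' window (equidistant ties resolved to the earlier date). Suppression and
#' CD4 flags are derived via [flag_outcomes()].
#'
#' @param patients Cohort tibble.
#' @param transfers Output of [classify_transfers()].
#' @param events Event tibble with canonical identifiers.
#' @param config An [analysis_config()].
#' @param years Which yearly time points to assess (subset of 1:3).
#' @return A tibble with one row per successful patient x year: eligibility,
#'   retention (`NA` when ineligible), window bounds, selected measurements
#'   and derived flags (`NA` when no measurement lies in the window).
#' @export
assess_timepoints <- function(patients, transfers, events,
                              config = analysis_config(), years = 1:3) {
  if (length(years) == 0 || !all(years %in% 1:3)) {
    abort("years must be a non-empty subset of 1:3")
  }
  succ <- transfers |>
    dplyr::filter(.data$success) |>
    dplyr::select("patient_id", "success_date") |>
    dplyr::inner_join(dplyr::select(patients, "patient_id",
                                    "origin_facility"),
                      by = "patient_id")
  grid <- tidyr::crossing(succ, year = as.integer(sort(years))) |>
    dplyr::mutate(
      target_date = .data$success_date + .data$year * config$year_days,
      window_start = .data$target_date - config$window_halfwidth_days,
      window_end = .data$target_date + config$window_halfwidth_days,
      eligible = as.numeric(config$closure_date - .data$success_date) >=
        (.data$year + 0.5) * 365.25
    )

  visits <- events |>
    dplyr::filter(.data$source == "visit") |>
    dplyr::inner_join(dplyr::select(patients, "patient_id",
                                    "origin_facility"),
                      by = "patient_id")
  if (!config$retention_counts_origin) {
    visits <- dplyr::filter(visits,
                            .data$facility != .data$origin_facility)
  }
  vis_hit <- grid |>
    dplyr::select("patient_id", "year", "window_start", "window_end") |>
    dplyr::inner_join(dplyr::select(visits, "patient_id", "date"),
                      by = "patient_id", relationship = "many-to-many") |>
    dplyr::filter(.data$date >= .data$window_start,
                  .data$date <= .data$window_end) |>
    dplyr::distinct(.data$patient_id, .data$year) |>
    dplyr::mutate(any_visit = TRUE)

  labs <- events |>
    dplyr::filter(.data$source == "lab",
                  .data$analyte %in% c("hiv_rna", "cd4"))
  sel <- grid |>
    dplyr::select("patient_id", "year", "target_date", "window_start",
                  "window_end") |>
    dplyr::inner_join(dplyr::select(labs, "patient_id", "date", "analyte",
                                    "value"),
                      by = "patient_id", relationship = "many-to-many") |>
    dplyr::filter(.data$date >= .data$window_start,
                  .data$date <= .data$window_end) |>
    dplyr::mutate(dist = abs(as.integer(.data$date - .data$target_date))) |>
    dplyr::group_by(.data$patient_id, .data$year, .data$analyte) |>
    dplyr::arrange(.data$dist, .data$date, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  lab_wide <- function(which, prefix) {
    sel |>
      dplyr::filter(.data$analyte == which) |>
      dplyr::select("patient_id", "year", "date", "value") |>
      stats::setNames(c("patient_id", "year", paste0(prefix, "_date"),
                        paste0(prefix, "_value")))
  }

  grid |>
    dplyr::left_join(vis_hit, by = c("patient_id", "year")) |>
    dplyr::left_join(lab_wide("hiv_rna", "vl"),
                     by = c("patient_id", "year")) |>
    dplyr::left_join(lab_wide("cd4", "cd4"), by = c("patient_id", "year")) |>
    dplyr::mutate(
      retained = dplyr::if_else(.data$eligible,
                                dplyr::coalesce(.data$any_visit, FALSE),
                                NA),
      vl_suppressed = flag_outcomes(.data$vl_value, "hiv_rna", config),
      cd4_above_500 = flag_outcomes(.data$cd4_value, "cd4", config)
    ) |>
    dplyr::select("patient_id", "year", "eligible", "retained",
                  "success_date", "target_date", "window_start", "window_end",
                  "vl_date", "vl_value", "vl_suppressed",
                  "cd4_date", "cd4_value", "cd4_above_500")
}

#' @rdname assess_timepoints
#' @param patient,outcome Single-row cohort and transfer-outcome tibbles;
#'   `outcome$success` must be `TRUE`.
#' @param year A single year in 1:3.
#' @return `assess_retention()` returns one row with `patient_id`, `year`,
#'   `eligible`, `retained`.
#' @export
assess_retention <- function(patient, outcome, events, year,
                             config = analysis_config()) {
  stopifnot(nrow(patient) == 1, nrow(outcome) == 1)
  if (length(year) != 1 || !year %in% 1:3) abort("year must be one of 1, 2, 3")
  if (!isTRUE(outcome$success)) abort("assess_retention requires a successful transfer")
  assess_timepoints(patient, outcome, events, config, years = year) |>
    dplyr::select("patient_id", "year", "eligible", "retained")
}

#' Select the laboratory measurement closest to a yearly time point
#'
#' Returns the measurement of `analyte` minimising the absolute distance to
#' the successful-transfer date plus `year` years, within the +/- 6-month
#' window; an equidistant tie goes to the earlier date. `NULL` when no
#' measurement falls in the window (reported downstream as missing).
#'
#' @inheritParams assess_retention
#' @param analyte `"hiv_rna"` or `"cd4"`.
#' @return A one-row tibble with `date` and `value`, or `NULL`.
#' @export
select_lab <- function(patient, outcome, events, analyte, year,
                       config = analysis_config()) {
  stopifnot(nrow(patient) == 1, nrow(outcome) == 1)
  if (!analyte %in% c("hiv_rna", "cd4")) abort("analyte must be hiv_rna or cd4")
  if (length(year) != 1 || !year %in% 1:3) abort("year must be one of 1, 2, 3")
  if (!isTRUE(outcome$success)) abort("select_lab requires a successful transfer")
  row <- assess_timepoints(patient, outcome, events, config, years = year)
  prefix <- if (analyte == "hiv_rna") "vl" else "cd4"
  date <- row[[paste0(prefix, "_date")]]
  if (is.na(date)) return(NULL)
  tibble::tibble(date = date, value = row[[paste0(prefix, "_value")]])
}

#' Threshold flags for laboratory values
#'
#' HIV-RNA is suppressed strictly below `suppression_threshold` (400
#' copies/ml by default). CD4 is flagged strictly above `cd4_threshold` (500
#' cells/ul) when `cd4_strict`, else at-or-above. Vectorised; `NA` in, `NA`
#' out.
#'
#' @param value Numeric vector of measurements.
#' @param analyte `"hiv_rna"` or `"cd4"`.
#' @param config An [analysis_config()].
#' @return Logical vector.
#' @export
#' @examples
#' flag_outcomes(c(399, 400), "hiv_rna")  # TRUE FALSE
#' flag_outcomes(500, "cd4")              # FALSE (strict)
flag_outcomes <- function(value, analyte, config = analysis_config()) {
  if (!analyte %in% c("hiv_rna", "cd4")) abort("analyte must be hiv_rna or cd4")
  if (analyte == "hiv_rna") {
    value < config$suppression_threshold
  } else if (config$cd4_strict) {
    value > config$cd4_threshold
  } else {
    value >= config$cd4_threshold
  }
}

#' Categorise a missing year-3 HIV-RNA
#'
#' Patients retained at year 3 but without an HIV-RNA in the year-3 window
#' are categorised, in priority order: `later_suppressed` (a suppressed
#' measurement within `missing_vl_horizon_days` after the window closes),
#' `previously_continuously_suppressed` (at least one post-transfer HIV-RNA
#' before the window opened, all of them suppressed), `later_unsuppressed`
#' (an unsuppressed measurement after the window), else `no_evidence`.
#'
#' @param patient Single-row cohort tibble.
#' @param events Event tibble with canonical identifiers.
#' @param year3_assessment The patient's year-3 row from
#'   [assess_timepoints()]; its `vl_value` must be missing.
#' @param config An [analysis_config()].
#' @return One of `"later_suppressed"`,
#'   `"previously_continuously_suppressed"`, `"later_unsuppressed"`,
#'   `"no_evidence"`.
#' @export
classify_missing_vl <- function(patient, events, year3_assessment,
                                config = analysis_config()) {
  stopifnot(nrow(patient) == 1, nrow(year3_assessment) == 1)
  if (year3_assessment$year != 3) abort("expected a year-3 assessment")
  if (!is.na(year3_assessment$vl_value)) {
    abort("patient has a year-3 HIV-RNA measurement; nothing to categorise")
  }
  thr <- config$suppression_threshold
  vls <- events |>
    dplyr::filter(.data$patient_id == patient$patient_id,
                  .data$source == "lab", .data$analyte == "hiv_rna",
                  .data$date > patient$transfer_out_date)
  w_end <- year3_assessment$window_end
  w_start <- year3_assessment$window_start
  later <- vls[vls$date > w_end, , drop = FALSE]
  shortly <- later[later$date <= w_end + config$missing_vl_horizon_days &
                     later$value < thr, , drop = FALSE]
  if (nrow(shortly) > 0) return("later_suppressed")
  prior <- vls[vls$date < w_start, , drop = FALSE]
  if (nrow(prior) > 0 && all(prior$value < thr)) {
    return("previously_continuously_suppressed")
  }
  if (any(later$value >= thr)) return("later_unsuppressed")
  "no_evidence"
}

#' Perinatal-infection proxy and age group at transfer
#'
#' Route of infection is rarely recorded in routine data; enrolment in HIV
#' care before `perinatal_cutoff_years` (13 by default, 10 as a stricter
#' alternative) proxies perinatal infection. Age at transfer is split at
#' `adolescent_age_split_years` into the 10-14 and 15-19 groups.
#'
#' @param patients Cohort tibble (any number of rows).
#' @param config An [analysis_config()].
#' @return `classify_perinatal()`: logical vector; `age_group()`: factor with
#'   levels `"10-14"`, `"15-19"`.
#' @export
classify_perinatal <- function(patients, config = analysis_config()) {
  patients$age_at_enrolment < config$perinatal_cutoff_years
}

#' @rdname classify_perinatal
#' @export
age_group <- function(patients, config = analysis_config()) {
  factor(ifelse(patients$age_at_transfer < config$adolescent_age_split_years,
                AGE_GROUPS[1], AGE_GROUPS[2]),
         levels = AGE_GROUPS)
}

#' Run the full ascertainment pipeline
#'
#' Validates inputs, resolves duplicate identifiers, classifies transfer
#' success and delay, and assesses retention and laboratory outcomes at
#' years 1-3.
#'
#' @param patients Cohort tibble.
#' @param events Event tibble.
#' @param duplicates Optional alias map tibble (`alias_id`, `canonical_id`).
#' @param config An [analysis_config()].
#' @return A list with `transfers` ([classify_transfers()] output),
#'   `timepoints` ([assess_timepoints()] output) and the `config` used.
#' @export
analyze_cohort <- function(patients, events, duplicates = NULL,
                           config = analysis_config()) {
  validate_cohort(patients)
  validate_events(events)
  if (!is.null(duplicates)) {
    events <- resolve_duplicates(events, duplicates)
  }
  transfers <- classify_transfers(patients, events, config)
  timepoints <- assess_timepoints(patients, transfers, events, config)
  list(transfers = transfers, timepoints = timepoints, config = config)
}
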