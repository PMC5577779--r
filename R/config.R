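#' Analysis configuration
#'
#' Bundles every constant the ascertainment pipeline depends on. Defaults
#' encode the study conventions: a 6-month ascertainment window of 183 days,
#' an 18-month linkage cut of 548 days, nominal years of 365 days (fractional
#' years of potential follow-up use 365.25 days/year), virologic suppression
#' below 400 copies/ml, an immunologic threshold of 500 cells/ul, a
#' perinatal-infection proxy of enrolment before 13 years, and the 10-14 vs
#' 15-19 age split at transfer. The database closure date defaults to
#' 2016-10-15 (mid-October closure of the data platform).
#'
#' @param closure_date Date at which the linked database closes; events and
#'   eligibility are assessed relative to this date.
#' @param window_halfwidth_days Half-width (days) of the window around each
#'   yearly time point for retention and laboratory selection.
#' @param months18_days Days corresponding to the 18-month linkage cut.
#' @param year_days Days per nominal year when locating yearly time points.
#' @param suppression_threshold HIV-RNA copies/ml below which a measurement
#'   counts as virologically suppressed (strict `<`).
#' @param cd4_threshold CD4 cells/ul above which a count is flagged.
#' @param cd4_strict If `TRUE` (default) the CD4 flag is strict (`> 500`);
#'   if `FALSE`, `>= 500` (the at-transfer descriptive convention).
#' @param perinatal_cutoff_years Enrolment age (years) below which a patient
#'   is taken as likely perinatally infected; 13 by default, 10 as the
#'   sensitivity alternative.
#' @param adolescent_age_split_years Age at transfer separating the 10-14 and
#'   15-19 groups.
#' @param source_subset Which event streams the classifier may use; any
#'   non-empty subset of `c("visit", "lab", "pharmacy")`.
#' @param strict_after_transfer If `TRUE` (default) a qualifying record must
#'   be strictly after the transfer-out date; same-day records at another
#'   facility are treated as pre-transfer administrative contacts.
#' @param retention_counts_origin If `TRUE`, visits back at the origin
#'   facility count towards retention; default `FALSE` (retention reflects
#'   engagement at the transfer destination).
#' @param missing_vl_horizon_days How far past the year-3 window a subsequent
#'   HIV-RNA may fall and still count as "shortly after" when categorising
#'   patients with a missing year-3 value.
#'
#' @return A list of class `analysis_config`.
#' @export
#' @examples
#' cfg <- analysis_config(source_subset = c("visit", "lab"))
#' cfg$months18_days
analysis_config <- function(closure_date = as.Date("2016-10-15"),
                            window_halfwidth_days = 183L,
                            months18_days = 548L,
                            year_days = 365L,
                            suppression_threshold = 400,
                            cd4_threshold = 500,
                            cd4_strict = TRUE,
                            perinatal_cutoff_years = 13,
                            adolescent_age_split_years = 15,
                            source_subset = SOURCES,
                            strict_after_transfer = TRUE,
                            retention_counts_origin = FALSE,
                            missing_vl_horizon_days = 183L) {
  closure_date <- as.Date(closure_date)
  source_subset <- as.character(source_subset)
  cfg <- structure(
    list(
      closure_date = closure_date,
      window_halfwidth_days = as.integer(window_halfwidth_days),
      months18_days = as.integer(months18_days),
      year_days = as.integer(year_days),
      suppression_threshold = as.numeric(suppression_threshold),
      cd4_threshold = as.numeric(cd4_threshold),
      cd4_strict = isTRUE(cd4_strict),
      perinatal_cutoff_years = as.numeric(perinatal_cutoff_years),
      adolescent_age_split_years = as.numeric(adolescent_age_split_years),
      source_subset = source_subset,
      strict_after_transfer = isTRUE(strict_after_transfer),
      retention_counts_origin = isTRUE(retention_counts_origin),
      missing_vl_horizon_days = as.integer(missing_vl_horizon_days)
    ),
    class = "analysis_config"
  )
  validate_analysis_config(cfg)
  cfg
}

validate_analysis_config <- function(cfg) {
  thresholds <- c(
    window_halfwidth_days = cfg$window_halfwidth_days,
    months18_days = cfg$months18_days,
    year_days = cfg$year_days,
    suppression_threshold = cfg$suppression_threshold,
    cd4_threshold = cfg$cd4_threshold,
    perinatal_cutoff_years = cfg$perinatal_cutoff_years,
    adolescent_age_split_years = cfg$adolescent_age_split_years,
    missing_vl_horizon_days = cfg$missing_vl_horizon_days
  )
  bad <- names(thresholds)[!is.finite(thresholds) | thresholds <= 0]
  if (length(bad) > 0) {
    abort(paste0("analysis_config thresholds must be positive: ",
                 paste(bad, collapse = ", ")))
  }
  if (length(cfg$source_subset) == 0 ||
      !all(cfg$source_subset %in% SOURCES)) {
    abort("source_subset must be a non-empty subset of visit/lab/pharmacy")
  }
  if (is.na(cfg$closure_date)) abort("closure_date must be a valid date")
  invisible(cfg)
}

#' Read or write an analysis configuration as YAML
#'
#' @param path Path to a YAML file holding any subset of the
#'   [analysis_config()] fields; omitted fields keep their defaults.
#' @return `read_analysis_config()` returns an `analysis_config`;
#'   `write_analysis_config()` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown analysis_config fields in ", path, ": ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(analysis_config, raw)
}

#' @rdname read_analysis_config
#' @param config An `analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  out <- unclass(config)
  out$closure_date <- format(out$closure_date)
  yaml::write_yaml(out, path)
  invisible(path)
}
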