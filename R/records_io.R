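# Column schemas for the three delimited inputs. Dates are ISO-8601; readr
# leaves unparseable dates as NA, which validation then reports per row.
COHORT_COLS <- readr::cols(
  patient_id = readr::col_character(),
  sex = readr::col_character(),
  enrolment_date = readr::col_date(format = "%Y-%m-%d"),
  art_start_date = readr::col_date(format = "%Y-%m-%d"),
  age_at_enrolment = readr::col_double(),
  age_at_art_start = readr::col_double(),
  age_at_transfer = readr::col_double(),
  transfer_out_date = readr::col_date(format = "%Y-%m-%d"),
  origin_facility = readr::col_character(),
  origin_level = readr::col_character(),
  cd4_at_transfer = readr::col_double(),
  vl_at_transfer = readr::col_double(),
  cd4_at_art_start = readr::col_double(),
  cd4pct_at_art_start = readr::col_double()
)

EVENT_COLS <- readr::cols(
  patient_id = readr::col_character(),
  facility = readr::col_character(),
  date = readr::col_date(format = "%Y-%m-%d"),
  source = readr::col_character(),
  analyte = readr::col_character(),
  value = readr::col_double()
)

DUPLICATE_COLS <- readr::cols(
  alias_id = readr::col_character(),
  canonical_id = readr::col_character()
)

required_names <- function(colspec) names(colspec$cols)

read_checked <- function(path, colspec, what) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(required_names(colspec), header)
  if (length(missing) > 0) {
    abort(paste0("schema error in ", path, " (", what, "): missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  readr::read_csv(path, col_types = colspec, show_col_types = FALSE)
}

# Collects row-indexed invariant violations and aborts if any; `checks` is a
# named list of logical vectors (TRUE = violated, NA treated as violated when
# na_bad, else ignored).
reject_rows <- function(tbl, checks, what, na_bad = TRUE) {
  msgs <- character(0)
  for (label in names(checks)) {
    bad <- checks[[label]]
    bad <- if (na_bad) bad | is.na(bad) else !is.na(bad) & bad
    idx <- which(bad)
    if (length(idx) > 0) {
      msgs <- c(msgs, paste0("  rows ", paste(head(idx, 20), collapse = ","),
                             if (length(idx) > 20) ",..." else "",
                             ": ", label))
    }
  }
  if (length(msgs) > 0) {
    abort(paste0("invalid ", what, " rows:\n", paste(msgs, collapse = "\n")))
  }
  invisible(tbl)
}

#' Validate a cohort table
#'
#' Checks the per-patient invariants: known sex and care level, parseable
#' dates in the order enrolment <= ART start <= transfer out, ages
#' non-decreasing in the same order, transfer between ages 10 and <20, and
#' unique patient identifiers. Violations are reported with row indices.
#'
#' @param patients A cohort tibble (see [read_cohort()]).
#' @return `patients`, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(patients) {
  reject_rows(patients, list(
    "missing/empty patient_id" =
      is.na(patients$patient_id) | patients$patient_id == "",
    "sex not male/female" = !patients$sex %in% c("male", "female"),
    "origin_level not primary/tertiary" =
      !patients$origin_level %in% c("primary", "tertiary"),
    "unparseable or missing date" =
      is.na(patients$enrolment_date) | is.na(patients$art_start_date) |
      is.na(patients$transfer_out_date),
    "dates out of order (need enrolment <= ART start <= transfer out)" =
      patients$enrolment_date > patients$art_start_date |
      patients$art_start_date > patients$transfer_out_date,
    "ages out of order" =
      patients$age_at_enrolment > patients$age_at_art_start |
      patients$age_at_art_start > patients$age_at_transfer,
    "age at transfer outside [10, 20)" =
      patients$age_at_transfer < 10 | patients$age_at_transfer >= 20,
    "duplicated patient_id" = duplicated(patients$patient_id)
  ), "cohort")
}

#' Validate an event table
#'
#' Enforces the event-stream invariants: source in visit/lab/pharmacy, a
#' laboratory analyte (with a non-negative value) present exactly when
#' `source == "lab"`, and parseable dates.
#'
#' @param events An event tibble (see [read_events()]).
#' @return `events`, invisibly, if valid; otherwise an error.
#' @export
validate_events <- function(events) {
  is_lab <- events$source == "lab"
  reject_rows(events, list(
    "missing/empty patient_id" =
      is.na(events$patient_id) | events$patient_id == "",
    "missing facility" = is.na(events$facility) | events$facility == "",
    "unparseable or missing date" = is.na(events$date),
    "source not visit/lab/pharmacy" = !events$source %in% SOURCES,
    "lab event must carry analyte hiv_rna/cd4" =
      !is.na(is_lab) & is_lab & !events$analyte %in% c("hiv_rna", "cd4"),
    "non-lab event must have analyte 'none'" =
      !is.na(is_lab) & !is_lab & !events$analyte %in% "none",
    "lab event must carry a non-negative value" =
      !is.na(is_lab) & is_lab & (is.na(events$value) | events$value < 0),
    "non-lab event must not carry a value" =
      !is.na(is_lab) & !is_lab & !is.na(events$value)
  ), "event", na_bad = FALSE)
}

#' Read and write the delimited analysis inputs
#'
#' Comma-separated, UTF-8, ISO-8601 dates, with a header. `read_cohort()` and
#' `read_events()` validate every row and reject files containing invariant
#' violations with row-indexed diagnostics; a missing column is a schema
#' error. Write/read round-trips are identity.
#'
#' @param path File path.
#' @return A tibble: one row per patient, event, or alias pair.
#' @export
read_cohort <- function(path) {
  tbl <- read_checked(path, COHORT_COLS, "cohort")
  validate_cohort(tbl)
  tbl
}

#' @rdname read_cohort
#' @export
read_events <- function(path) {
  tbl <- read_checked(path, EVENT_COLS, "events")
  validate_events(tbl)
  tbl
}

#' @rdname read_cohort
#' @export
read_duplicates <- function(path) {
  tbl <- read_checked(path, DUPLICATE_COLS, "duplicates")
  reject_rows(tbl, list(
    "missing alias_id" = is.na(tbl$alias_id) | tbl$alias_id == "",
    "missing canonical_id" = is.na(tbl$canonical_id) | tbl$canonical_id == "",
    "alias mapped to itself" = tbl$alias_id == tbl$canonical_id,
    "alias mapped to two targets" = duplicated(tbl$alias_id)
  ), "duplicate-map")
  tbl
}

#' @rdname read_cohort
#' @param x The tibble to write.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname read_cohort
#' @export
write_events <- function(x, path) {
  validate_events(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname read_cohort
#' @export
write_duplicates <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

# Transitively resolves an alias -> canonical map to a flat lookup in which
# every alias points at a terminal identifier. Cycles are a configuration
# error; chains (an alias whose target is itself an alias) resolve with a
# warning.
flatten_duplicate_map <- function(duplicates) {
  if (nrow(duplicates) == 0) return(character(0))
  map <- setNames(duplicates$canonical_id, duplicates$alias_id)
  if (any(duplicates$canonical_id %in% duplicates$alias_id)) {
    warn("duplicate map contains chained aliases; resolving transitively")
  }
  resolved <- map
  for (step in seq_len(length(map) + 1)) {
    hop <- resolved %in% names(map)
    if (!any(hop)) break
    if (step > length(map)) {
      abort("duplicate map contains a cycle; cannot resolve identifiers")
    }
    resolved[hop] <- map[resolved[hop]]
  }
  if (any(resolved %in% names(map))) {
    abort("duplicate map contains a cycle; cannot resolve identifiers")
  }
  resolved
}

#' Replace alias identifiers with canonical ones
#'
#' Patients occasionally accumulate more than one identifier in error; the
#' health-information platform publishes alias pairs once the link is
#' demonstrated. This rewrites every event's `patient_id` through the
#' transitive closure of the alias map, yielding one canonical event stream
#' per individual. Idempotent; all non-identifier fields and the event count
#' are unchanged.
#'
#' @param events An event tibble.
#' @param duplicates A tibble with columns `alias_id`, `canonical_id`, acyclic
#'   after transitive closure.
#' @return `events` with canonical `patient_id`s.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = "B", facility = "F1", date = as.Date("2010-01-01"),
#'   source = "visit", analyte = "none", value = NA_real_
#' )
#' dup <- tibble::tibble(alias_id = "B", canonical_id = "A")
#' resolve_duplicates(ev, dup)$patient_id
resolve_duplicates <- function(events, duplicates) {
  lookup <- flatten_duplicate_map(duplicates)
  if (length(lookup) == 0) return(events)
  hit <- events$patient_id %in% names(lookup)
  events$patient_id[hit] <- unname(lookup[events$patient_id[hit]])
  events
}
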