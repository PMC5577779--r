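#' Configuration of the synthetic cohort generator
#'
#' Parameters of the data-generating process used to emulate a provincial
#' health-data-platform extract for transferred adolescents: a cohort table,
#' per-source event streams (visits, laboratory, pharmacy), an
#' identifier-duplicate map, and a latent truth table for parameter-recovery
#' testing. Defaults encode the study conditions: 53.3% female, 72.2%
#' transferring at 10-14 years, 79.3% from tertiary care, about 5%
#' transferring out of the observed system, an 85% linkage probability for
#' in-scope transfers, a log-normal transfer delay with median 56 days and
#' sigma matched to the 27-134 day interquartile range, visits every 84 days
#' on average, per-year laboratory completeness declining from 89%/87%
#' (HIV-RNA/CD4) at year 1 to 80%/72% at year 3, 80% of measured HIV-RNA
#' suppressed, per-contact stream capture of 95%/85%/55%
#' (visit/lab/pharmacy), and a 2% rate of split identifiers.
#'
#' @param n_patients Number of patients (>= 0).
#' @param seed Integer seed; identical (config, seed) gives identical output.
#' @param p_female,p_young_transfer,p_tertiary Demographic mix.
#' @param p_out_of_scope Probability the transfer leaves the observed system
#'   entirely (no post-transfer events anywhere).
#' @param p_success_given_in_scope Probability an in-scope transfer links to
#'   a new facility.
#' @param delay_lognormal_median_days,delay_lognormal_sigma Log-normal
#'   transfer-delay parameters; the default sigma is
#'   `log(134/27) / (2 * qnorm(0.75))` so the quartiles sit at 27 and 134
#'   days when the median is 56.
#' @param visit_interval_days Mean gap between post-transfer visits
#'   (exponential gaps).
#' @param annual_dropout_hazard Per-year probability of stopping all care.
#' @param p_vl_measured_by_year,p_cd4_measured_by_year Length-3 probabilities
#'   that the year-1/2/3 laboratory measurement happens at all.
#' @param p_suppressed Probability a measured HIV-RNA is below 400 copies/ml.
#' @param suppression_markov,suppression_persistence If `TRUE`, successive
#'   HIV-RNA states follow a two-state Markov chain with the given
#'   persistence instead of i.i.d. draws.
#' @param source_coverage Named per-contact capture probabilities for the
#'   `visit`, `lab` and `pharmacy` streams.
#' @param p_duplicate_id Probability a linked patient's post-transfer events
#'   are recorded under a second (alias) identifier.
#' @param p_origin_return_if_unlinked Probability an unlinked in-scope
#'   patient bounces back to the origin facility after transfer-out (events
#'   that must never count as successful transfer).
#' @param p_late_vl_after3 Probability that a patient who skipped the year-3
#'   HIV-RNA gets one shortly after the window closes.
#' @param study_start,study_end Transfer-out dates are uniform over this
#'   range.
#' @param closure_date Database closure; no emitted event is dated later.
#' @return A list of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(n_patients,
                              seed = 1L,
                              p_female = 0.533,
                              p_young_transfer = 0.722,
                              p_tertiary = 0.793,
                              p_out_of_scope = 0.05,
                              p_success_given_in_scope = 0.85,
                              delay_lognormal_median_days = 56,
                              delay_lognormal_sigma =
                                log(134 / 27) / (2 * stats::qnorm(0.75)),
                              visit_interval_days = 84,
                              annual_dropout_hazard = 0.05,
                              p_vl_measured_by_year = c(0.89, 0.845, 0.80),
                              p_cd4_measured_by_year = c(0.87, 0.795, 0.72),
                              p_suppressed = 0.80,
                              suppression_markov = FALSE,
                              suppression_persistence = 0.9,
                              source_coverage = c(visit = 0.95, lab = 0.85,
                                                  pharmacy = 0.55),
                              p_duplicate_id = 0.02,
                              p_origin_return_if_unlinked = 0.3,
                              p_late_vl_after3 = 0.4,
                              study_start = as.Date("2004-03-01"),
                              study_end = as.Date("2014-12-31"),
                              closure_date = as.Date("2016-10-15")) {
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      p_female = p_female, p_young_transfer = p_young_transfer,
      p_tertiary = p_tertiary, p_out_of_scope = p_out_of_scope,
      p_success_given_in_scope = p_success_given_in_scope,
      delay_lognormal_median_days = delay_lognormal_median_days,
      delay_lognormal_sigma = delay_lognormal_sigma,
      visit_interval_days = visit_interval_days,
      annual_dropout_hazard = annual_dropout_hazard,
      p_vl_measured_by_year = p_vl_measured_by_year,
      p_cd4_measured_by_year = p_cd4_measured_by_year,
      p_suppressed = p_suppressed,
      suppression_markov = isTRUE(suppression_markov),
      suppression_persistence = suppression_persistence,
      source_coverage = source_coverage,
      p_duplicate_id = p_duplicate_id,
      p_origin_return_if_unlinked = p_origin_return_if_unlinked,
      p_late_vl_after3 = p_late_vl_after3,
      study_start = as.Date(study_start), study_end = as.Date(study_end),
      closure_date = as.Date(closure_date)
    ),
    class = "cohort_gen_config"
  )
  validate_gen_config(cfg)
  cfg
}

validate_gen_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 0) {
    abort("n_patients must be a non-negative integer")
  }
  if (length(cfg$p_vl_measured_by_year) != 3 ||
      length(cfg$p_cd4_measured_by_year) != 3) {
    abort("per-year lab completeness must have length 3 (years 1-3)")
  }
  if (!all(SOURCES %in% names(cfg$source_coverage))) {
    abort("source_coverage must name visit, lab and pharmacy")
  }
  probs <- c(
    p_female = cfg$p_female, p_young_transfer = cfg$p_young_transfer,
    p_tertiary = cfg$p_tertiary, p_out_of_scope = cfg$p_out_of_scope,
    p_success_given_in_scope = cfg$p_success_given_in_scope,
    annual_dropout_hazard = cfg$annual_dropout_hazard,
    p_suppressed = cfg$p_suppressed,
    suppression_persistence = cfg$suppression_persistence,
    p_duplicate_id = cfg$p_duplicate_id,
    p_origin_return_if_unlinked = cfg$p_origin_return_if_unlinked,
    p_late_vl_after3 = cfg$p_late_vl_after3,
    stats::setNames(cfg$p_vl_measured_by_year,
                    paste0("p_vl_measured_by_year", 1:3)),
    stats::setNames(cfg$p_cd4_measured_by_year,
                    paste0("p_cd4_measured_by_year", 1:3)),
    stats::setNames(cfg$source_coverage,
                    paste0("source_coverage_", names(cfg$source_coverage)))
  )
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad) > 0) {
    abort(paste0("probabilities must lie in [0, 1]: ",
                 paste(bad, collapse = ", ")))
  }
  if (cfg$delay_lognormal_median_days <= 0 || cfg$delay_lognormal_sigma <= 0 ||
      cfg$visit_interval_days <= 0) {
    abort("delay and visit-interval parameters must be positive")
  }
  if (cfg$study_start > cfg$study_end || cfg$study_end > cfg$closure_date) {
    abort("need study_start <= study_end <= closure_date")
  }
  invisible(cfg)
}

empty_patients <- function() {
  tibble::tibble(patient_id = character(), sex = character(),
                 enrolment_date = as.Date(character()),
                 art_start_date = as.Date(character()),
                 age_at_enrolment = double(), age_at_art_start = double(),
                 age_at_transfer = double(),
                 transfer_out_date = as.Date(character()),
                 origin_facility = character(), origin_level = character(),
                 cd4_at_transfer = double(), vl_at_transfer = double(),
                 cd4_at_art_start = double(), cd4pct_at_art_start = double())
}

empty_events <- function() {
  tibble::tibble(patient_id = character(), facility = character(),
                 date = as.Date(character()), source = character(),
                 analyte = character(), value = double())
}

empty_truth <- function() {
  tibble::tibble(patient_id = character(), in_scope = logical(),
                 success = logical(), true_delay_days = integer(),
                 success_date = as.Date(character()),
                 true_retained_y1 = logical(), true_retained_y2 = logical(),
                 true_retained_y3 = logical(),
                 true_vl_suppressed_y1 = logical(),
                 true_vl_suppressed_y2 = logical(),
                 true_vl_suppressed_y3 = logical())
}

# Log-normal draw matched to a printed median and IQR: meanlog = log(median),
# sdlog = log(q3/q1) / (2 * qnorm(0.75)).
rlnorm_median_iqr <- function(n, med, q1, q3) {
  rlnorm(n, meanlog = log(med),
         sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

ORIGIN_TERTIARY <- c("TERT-A", "TERT-B")
ORIGIN_PRIMARY <- c("PHC-A", "PHC-B")
DEST_FACILITIES <- sprintf("CLIN-%02d", 1:40)

#' Generate a synthetic linked cohort
#'
#' Simulates the full observation process: latent transfer success and delay
#' (truncated at database closure, so a latent success always has an
#' observable first contact),
#' a post-transfer visit process with exponential gaps and attrition, yearly
#' laboratory measurements with completeness declining over time,
#' per-contact capture into the three event streams (pharmacy dispensing
#' occurs only on visit dates), sparse pre-transfer contacts at the origin
#' facility, origin-facility "bounce-back" visits for unlinked patients,
#' out-of-system transfers that emit no post-transfer events, and occasional
#' split identifiers recorded in the duplicate map. The latent state of every
#' patient is returned in `truth` so that downstream estimates can be checked
#' against the generating parameters.
#'
#' @param config A [cohort_gen_config()].
#' @return A list with tibbles `patients`, `events`, `duplicates`
#'   (`alias_id`, `canonical_id`) and `truth`.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_gen_config(n_patients = 20, seed = 7))
#' nrow(sim$patients)
generate_cohort <- function(config) {
  validate_gen_config(config)
  n <- config$n_patients
  if (n == 0) {
    return(list(
      patients = empty_patients(),
      events = empty_events(),
      duplicates = tibble::tibble(alias_id = character(),
                                  canonical_id = character()),
      truth = empty_truth()
    ))
  }
  set.seed(config$seed)
  cov <- config$source_coverage

  patient_id <- sprintf("P%05d", seq_len(n))
  sex <- ifelse(runif(n) < config$p_female, "female", "male")
  young <- runif(n) < config$p_young_transfer
  tertiary <- runif(n) < config$p_tertiary
  origin_facility <- ifelse(
    tertiary,
    sample(ORIGIN_TERTIARY, n, replace = TRUE),
    sample(ORIGIN_PRIMARY, n, replace = TRUE)
  )
  origin_level <- ifelse(tertiary, "tertiary", "primary")
  span <- as.integer(config$study_end - config$study_start)
  transfer_out_date <- config$study_start +
    sample.int(span + 1L, n, replace = TRUE) - 1L
  age_at_transfer <- ifelse(young, runif(n, 10, 15), runif(n, 15, 20))
  # Time on ART at transfer matched to the cohort's median/IQR (5.5, 1.5-8.2
  # years), truncated so ART starts at a plausible age.
  years_on_art <- pmin(pmax(rlnorm_median_iqr(n, 5.5, 1.5, 8.2), 0.25),
                       age_at_transfer - 0.5)
  age_at_art_start <- age_at_transfer - years_on_art
  age_at_enrolment <- pmax(age_at_art_start - runif(n, 0, 0.3), 0.1)
  enrolment_date <- transfer_out_date -
    round((age_at_transfer - age_at_enrolment) * 365.25)
  art_start_date <- transfer_out_date -
    round((age_at_transfer - age_at_art_start) * 365.25)

  cd4_at_art_start <- ifelse(runif(n) < 0.9,
                             round(rlnorm_median_iqr(n, 289, 161, 537)),
                             NA_real_)
  cd4pct_at_art_start <- ifelse(is.na(cd4_at_art_start), NA_real_,
                                pmin(round(
                                  rlnorm_median_iqr(n, 12.8, 7.1, 19.8), 1),
                                  45))
  cd4_at_transfer <- ifelse(runif(n) < 0.97,
                            round(rlnorm_median_iqr(n, 636, 387, 876)),
                            NA_real_)
  vl_measured_at_transfer <- runif(n) < 0.943
  vl_suppressed_at_transfer <- runif(n) < 0.779
  vl_at_transfer <- ifelse(
    vl_measured_at_transfer,
    ifelse(vl_suppressed_at_transfer,
           pmin(round(exp(runif(n, log(20), log(400)))), 399),
           round(exp(runif(n, log(400), log(5e5))))),
    NA_real_
  )

  in_scope <- runif(n) >= config$p_out_of_scope
  success <- in_scope & (runif(n) < config$p_success_given_in_scope)
  # A "successful" transfer means the patient is observed at the new site
  # before database closure, so the delay draw is the configured log-normal
  # truncated at each patient's remaining observation time (the study window
  # ends well before closure, leaving every patient at least ~1.8 years).
  true_delay <- rep(NA_real_, n)
  idx <- which(success)
  if (length(idx) > 0) {
    max_delay <- as.numeric(config$closure_date - transfer_out_date[idx])
    d <- pmax(1, round(rlnorm(length(idx),
                              log(config$delay_lognormal_median_days),
                              config$delay_lognormal_sigma)))
    for (tries in 1:1000) {
      late <- d > max_delay
      if (!any(late)) break
      d[late] <- pmax(1, round(rlnorm(sum(late),
                                      log(config$delay_lognormal_median_days),
                                      config$delay_lognormal_sigma)))
    }
    d <- pmin(d, max_delay)
    true_delay[idx] <- d
  }
  success_date <- transfer_out_date + true_delay
  dest <- sample(DEST_FACILITIES, n, replace = TRUE)
  dup <- success & runif(n) < config$p_duplicate_id
  dropout_rate_day <- -log(1 - config$annual_dropout_hazard) / 365.25

  ev_pid <- vector("list", n); ev_fac <- vector("list", n)
  ev_date <- vector("list", n); ev_src <- vector("list", n)
  ev_analyte <- vector("list", n); ev_val <- vector("list", n)
  true_ret <- matrix(NA, n, 3)
  true_sup <- matrix(NA, n, 3)
  alias_of <- rep(NA_character_, n)
  closure_num <- as.numeric(config$closure_date)

  draw_vl_value <- function(suppressed) {
    if (suppressed) min(round(exp(runif(1, log(20), log(400)))), 399)
    else round(exp(runif(1, log(400), log(5e5))))
  }

  for (i in seq_len(n)) {
    pid <- character(0); fac <- character(0); dt <- numeric(0)
    src <- character(0); ana <- character(0); val <- numeric(0)
    t_out <- as.numeric(transfer_out_date[i])
    enrol <- as.numeric(enrolment_date[i])
    add <- function(facility, date, source, analyte = "none",
                    value = NA_real_, id = patient_id[i]) {
      pid <<- c(pid, id); fac <<- c(fac, facility); dt <<- c(dt, date)
      src <<- c(src, source); ana <<- c(ana, analyte); val <<- c(val, value)
    }

    # Sparse pre-transfer contacts at the origin facility; the last one
    # anchors the last-contact delay definition.
    n_pre <- 1 + rpois(1, 1)
    offs <- sample(0:45, 1) + c(0, cumsum(pmax(30, round(
      rexp(max(n_pre - 1, 0), 1 / 120)))))
    pre_dates <- pmax(t_out - offs, enrol)
    for (d in pre_dates) {
      if (runif(1) < cov["visit"]) add(origin_facility[i], d, "visit")
    }
    if (!is.na(vl_at_transfer[i]) && runif(1) < cov["lab"]) {
      add(origin_facility[i], max(t_out - sample(0:30, 1), enrol), "lab",
          "hiv_rna", vl_at_transfer[i])
    }
    if (!is.na(cd4_at_transfer[i]) && runif(1) < cov["lab"]) {
      add(origin_facility[i], max(t_out - sample(0:30, 1), enrol), "lab",
          "cd4", cd4_at_transfer[i])
    }

    if (success[i]) {
      post_id <- if (dup[i]) paste0(patient_id[i], "-B") else patient_id[i]
      if (dup[i]) alias_of[i] <- post_id
      s_date <- as.numeric(success_date[i])
      dropout_days <- rexp(1, dropout_rate_day)
      # Generate occasions past closure so latent retention is well defined
      # even for late transfers; emitted events are clipped at closure.
      horizon <- min(dropout_days,
                     max(closure_num - s_date, 3 * 365 + 183 + 30))
      occ <- 0
      repeat {
        gap <- max(1, round(rexp(1, 1 / config$visit_interval_days)))
        nxt <- if (length(occ) == 0) 0 else occ[length(occ)] + gap
        if (nxt > horizon) break
        occ <- c(occ, nxt)
      }
      occ_dates <- s_date + occ
      for (d in occ_dates[occ_dates <= closure_num]) {
        if (runif(1) < cov["visit"]) add(dest[i], d, "visit", id = post_id)
        if (runif(1) < cov["pharmacy"]) add(dest[i], d, "pharmacy",
                                            id = post_id)
      }
      for (y in 1:3) {
        true_ret[i, y] <- any(occ >= y * 365 - 183 & occ <= y * 365 + 183)
      }

      sup_state <- runif(1) < config$p_suppressed
      vl_missing_y3 <- FALSE
      for (y in 1:3) {
        lab_off <- y * 365 + sample(-120:120, 1)
        in_care <- lab_off <= horizon
        if (in_care && runif(1) < config$p_vl_measured_by_year[y]) {
          if (config$suppression_markov && y > 1) {
            sup_state <- if (sup_state) {
              runif(1) < config$suppression_persistence
            } else {
              runif(1) < 1 - config$suppression_persistence
            }
          } else if (!config$suppression_markov) {
            sup_state <- runif(1) < config$p_suppressed
          }
          true_sup[i, y] <- sup_state
          d <- s_date + lab_off
          if (d <= closure_num && runif(1) < cov["lab"]) {
            add(dest[i], d, "lab", "hiv_rna", draw_vl_value(sup_state),
                id = post_id)
          }
        } else if (y == 3) {
          vl_missing_y3 <- in_care
        }
        if (in_care && runif(1) < config$p_cd4_measured_by_year[y]) {
          d <- s_date + y * 365 + sample(-120:120, 1)
          if (d <= closure_num && runif(1) < cov["lab"]) {
            add(dest[i], d, "lab", "cd4",
                round(rlnorm_median_iqr(1, 620, 430, 900)), id = post_id)
          }
        }
      }
      # Patients who skipped the year-3 HIV-RNA often test shortly after the
      # window closes (stable patients on stretched visit schedules).
      if (vl_missing_y3 && runif(1) < config$p_late_vl_after3) {
        d <- s_date + 3 * 365 + 183 + sample(1:150, 1)
        if (d <= min(closure_num, s_date + horizon) &&
            runif(1) < cov["lab"]) {
          add(dest[i], d, "lab", "hiv_rna",
              draw_vl_value(runif(1) < config$p_suppressed), id = post_id)
        }
      }
    } else if (in_scope[i] &&
               runif(1) < config$p_origin_return_if_unlinked) {
      # Unlinked but still in the system: bounce-back visits at the origin
      # facility, which must never count as successful transfer.
      for (d in t_out + sample(30:400, 1 + rbinom(1, 1, 0.5))) {
        if (d <= closure_num && runif(1) < cov["visit"]) {
          add(origin_facility[i], d, "visit")
        }
      }
    }

    ev_pid[[i]] <- pid; ev_fac[[i]] <- fac; ev_date[[i]] <- dt
    ev_src[[i]] <- src; ev_analyte[[i]] <- ana; ev_val[[i]] <- val
  }

  patients <- tibble::tibble(
    patient_id = patient_id, sex = sex,
    enrolment_date = enrolment_date, art_start_date = art_start_date,
    age_at_enrolment = round(age_at_enrolment, 2),
    age_at_art_start = round(age_at_art_start, 2),
    age_at_transfer = pmin(round(age_at_transfer, 2), 19.99),
    transfer_out_date = transfer_out_date,
    origin_facility = origin_facility, origin_level = origin_level,
    cd4_at_transfer = cd4_at_transfer, vl_at_transfer = vl_at_transfer,
    cd4_at_art_start = cd4_at_art_start,
    cd4pct_at_art_start = cd4pct_at_art_start
  )
  events <- tibble::tibble(
    patient_id = unlist(ev_pid, use.names = FALSE),
    facility = unlist(ev_fac, use.names = FALSE),
    date = as.Date(unlist(ev_date, use.names = FALSE),
                   origin = "1970-01-01"),
    source = unlist(ev_src, use.names = FALSE),
    analyte = unlist(ev_analyte, use.names = FALSE),
    value = unlist(ev_val, use.names = FALSE)
  )
  if (nrow(events) == 0) events <- empty_events()
  duplicates <- tibble::tibble(
    alias_id = alias_of[!is.na(alias_of)],
    canonical_id = patient_id[!is.na(alias_of)]
  )
  truth <- tibble::tibble(
    patient_id = patient_id, in_scope = in_scope, success = success,
    true_delay_days = as.integer(true_delay), success_date = success_date,
    true_retained_y1 = true_ret[, 1], true_retained_y2 = true_ret[, 2],
    true_retained_y3 = true_ret[, 3],
    true_vl_suppressed_y1 = true_sup[, 1],
    true_vl_suppressed_y2 = true_sup[, 2],
    true_vl_suppressed_y3 = true_sup[, 3]
  )
  list(patients = patients, events = events, duplicates = duplicates,
       truth = truth)
}

#' Summarise the latent truth table
#'
#' True proportions with their denominators: transfer success, linkage within
#' 18 months, retention at years 1-3 (among latent successes) and HIV-RNA
#' suppression at years 1-3 (among latent measurements).
#'
#' @param truth The `truth` tibble from [generate_cohort()].
#' @param months18_days Days defining the 18-month cut (548 by default).
#' @return A tibble with columns `measure`, `numerator`, `denominator`,
#'   `proportion`.
#' @export
truth_summary <- function(truth, months18_days = 548L) {
  if (nrow(truth) == 0) abort("truth table is empty")
  row <- function(measure, num, den) {
    tibble::tibble(measure = measure, numerator = num, denominator = den,
                   proportion = ifelse(den > 0, num / den, NA_real_))
  }
  succ <- truth[truth$success, , drop = FALSE]
  out <- dplyr::bind_rows(
    row("success", sum(truth$success), nrow(truth)),
    row("success_within_18mo",
        sum(succ$true_delay_days <= months18_days), nrow(succ))
  )
  for (y in 1:3) {
    ret <- succ[[paste0("true_retained_y", y)]]
    sup <- succ[[paste0("true_vl_suppressed_y", y)]]
    out <- dplyr::bind_rows(
      out,
      row(paste0("retained_y", y), sum(ret), length(ret)),
      row(paste0("vl_suppressed_y", y), sum(sup, na.rm = TRUE),
          sum(!is.na(sup)))
    )
  }
  out
}

#' Write a generated cohort to a directory
#'
#' Emits `patients.csv`, `events.csv`, `duplicates.csv` and `truth.csv`.
#'
#' @param sim Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cohort(sim$patients, file.path(dir, "patients.csv"))
  write_events(sim$events, file.path(dir, "events.csv"))
  write_duplicates(sim$duplicates, file.path(dir, "duplicates.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
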