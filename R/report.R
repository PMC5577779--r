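# Round half away from zero (display convention for report tables).
round_half_up <- function(x, digits = 0) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Cohort characteristics stratified by transfer success
#'
#' A tidy version of the familiar baseline table: each row is one variable
#' level (or one median summary) in one stratum (`successful`,
#' `not_successful`, `all`), with the numerator and denominator from which
#' every percentage is computed, so the table is fully recomputable.
#' Categorical rows: sex, enrolment age relative to the perinatal proxy
#' cutoff, age group at transfer, origin care level, and the at-transfer
#' HIV-RNA and CD4 flags (denominators are patients with the measurement).
#' Median rows: ages at ART start and transfer, years on ART, CD4 at ART
#' start and transfer, CD4% at ART start.
#'
#' @param patients Cohort tibble.
#' @param transfers Output of [classify_transfers()].
#' @param config An [analysis_config()].
#' @return A tibble: `variable`, `level`, `stratum`, `numerator`,
#'   `denominator`, `pct`, `median`, `q1`, `q3`.
#' @export
build_table1 <- function(patients, transfers, config = analysis_config()) {
  df <- patients |>
    dplyr::inner_join(dplyr::select(transfers, "patient_id", "success"),
                      by = "patient_id") |>
    dplyr::mutate(
      years_on_art = as.numeric(.data$transfer_out_date -
                                  .data$art_start_date) / 365.25,
      vl_supp = flag_outcomes(.data$vl_at_transfer, "hiv_rna", config),
      cd4_above = flag_outcomes(.data$cd4_at_transfer, "cd4", config),
      perinatal = classify_perinatal(patients, config),
      agegrp = age_group(patients, config)
    )
  strata <- list(successful = df[df$success, ],
                 not_successful = df[!df$success, ],
                 all = df)
  cat_row <- function(d, variable, level, flag) {
    tibble::tibble(variable = variable, level = level,
                   numerator = sum(flag, na.rm = TRUE),
                   denominator = sum(!is.na(flag)),
                   pct = 100 * sum(flag, na.rm = TRUE) /
                     max(sum(!is.na(flag)), 1),
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_)
  }
  med_row <- function(d, variable, x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    tibble::tibble(variable = variable, level = "median (IQR)",
                   numerator = NA_integer_, denominator = sum(!is.na(x)),
                   pct = NA_real_, median = q[2], q1 = q[1], q3 = q[3])
  }
  peri_lab <- paste0("enrolled <", config$perinatal_cutoff_years, "y")
  one_stratum <- function(d) {
    dplyr::bind_rows(
      tibble::tibble(variable = "patients", level = "n",
                     numerator = nrow(d), denominator = nrow(df),
                     pct = 100 * nrow(d) / max(nrow(df), 1),
                     median = NA_real_, q1 = NA_real_, q3 = NA_real_),
      cat_row(d, "sex", "male", d$sex == "male"),
      cat_row(d, "sex", "female", d$sex == "female"),
      cat_row(d, "age_at_enrolment", peri_lab, d$perinatal),
      cat_row(d, "age_at_enrolment", "at/after cutoff", !d$perinatal),
      cat_row(d, "age_at_transfer_group", AGE_GROUPS[1],
              d$agegrp == AGE_GROUPS[1]),
      cat_row(d, "age_at_transfer_group", AGE_GROUPS[2],
              d$agegrp == AGE_GROUPS[2]),
      cat_row(d, "origin_level", "primary", d$origin_level == "primary"),
      cat_row(d, "origin_level", "tertiary", d$origin_level == "tertiary"),
      cat_row(d, "vl_at_transfer", "<400 copies/ml", d$vl_supp),
      cat_row(d, "cd4_at_transfer_flag", "above threshold", d$cd4_above),
      med_row(d, "age_at_art_start", d$age_at_art_start),
      med_row(d, "cd4_at_art_start", d$cd4_at_art_start),
      med_row(d, "cd4pct_at_art_start", d$cd4pct_at_art_start),
      med_row(d, "age_at_transfer", d$age_at_transfer),
      med_row(d, "years_on_art_at_transfer", d$years_on_art),
      med_row(d, "cd4_at_transfer", d$cd4_at_transfer)
    )
  }
  purrr::imap(strata, function(d, nm) {
    dplyr::mutate(one_stratum(d), stratum = nm)
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("stratum", .after = "level")
}

#' Yearly outcome percentages overall and by age group at transfer
#'
#' For each year (1-3) and group (`all`, `10-14`, `15-19`): the percentage
#' retained among those eligible; and, among the retained, the percentages
#' with an HIV-RNA / CD4 measurement, missing each measurement, suppressed
#' and above the CD4 threshold — the latter two both as a percentage of
#' those assessed (the primary denominator) and of all retained. Every row
#' carries its numerator and denominator.
#'
#' @param patients Cohort tibble.
#' @param transfers Output of [classify_transfers()].
#' @param timepoints Output of [assess_timepoints()].
#' @param config An [analysis_config()].
#' @return A tibble: `year`, `group`, `measure`, `numerator`, `denominator`,
#'   `pct`.
#' @export
build_figure2 <- function(patients, transfers, timepoints,
                          config = analysis_config()) {
  tp <- timepoints |>
    dplyr::inner_join(
      tibble::tibble(patient_id = patients$patient_id,
                     agegrp = as.character(age_group(patients, config))),
      by = "patient_id"
    )
  groups <- c(list(all = tp),
              split(tp, tp$agegrp))
  purrr::imap(groups, function(d, nm) {
    purrr::map(sort(unique(d$year)), function(y) {
      dy <- d[d$year == y & d$eligible, , drop = FALSE]
      ret <- dy[which(dy$retained), , drop = FALSE]
      measure_row <- function(measure, num, den) {
        tibble::tibble(year = y, group = nm, measure = measure,
                       numerator = num, denominator = den,
                       pct = ifelse(den > 0, 100 * num / den, NA_real_))
      }
      dplyr::bind_rows(
        measure_row("retained", sum(dy$retained), nrow(dy)),
        measure_row("vl_measured", sum(!is.na(ret$vl_value)), nrow(ret)),
        measure_row("missing_vl", sum(is.na(ret$vl_value)), nrow(ret)),
        measure_row("vl_suppressed_of_assessed",
                    sum(ret$vl_suppressed, na.rm = TRUE),
                    sum(!is.na(ret$vl_value))),
        measure_row("vl_suppressed_of_retained",
                    sum(ret$vl_suppressed, na.rm = TRUE), nrow(ret)),
        measure_row("cd4_measured", sum(!is.na(ret$cd4_value)), nrow(ret)),
        measure_row("missing_cd4", sum(is.na(ret$cd4_value)), nrow(ret)),
        measure_row("cd4_above_of_assessed",
                    sum(ret$cd4_above_500, na.rm = TRUE),
                    sum(!is.na(ret$cd4_value))),
        measure_row("cd4_above_of_retained",
                    sum(ret$cd4_above_500, na.rm = TRUE), nrow(ret))
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Chi-square comparisons of yearly outcomes between age groups
#'
#' Pearson chi-square (no continuity correction) comparing the 10-14 and
#' 15-19 groups for each year and each of retention, suppression among
#' assessed, and CD4 above threshold among assessed.
#'
#' @param figure2 Output of [build_figure2()].
#' @return A tibble: `year`, `measure`, `p_value`, `statistic`.
#' @export
figure2_group_tests <- function(figure2) {
  measures <- c("retained", "vl_suppressed_of_assessed",
                "cd4_above_of_assessed")
  grid <- tidyr::expand_grid(year = sort(unique(figure2$year)),
                             measure = measures)
  purrr::pmap(grid, function(year, measure) {
    g1 <- figure2[figure2$year == year & figure2$measure == measure &
                    figure2$group == AGE_GROUPS[1], ]
    g2 <- figure2[figure2$year == year & figure2$measure == measure &
                    figure2$group == AGE_GROUPS[2], ]
    res <- if (nrow(g1) == 1 && nrow(g2) == 1 &&
               g1$denominator > 0 && g2$denominator > 0) {
      group_compare(g1$numerator, g1$denominator,
                    g2$numerator, g2$denominator)
    } else {
      list(p_value = NA_real_, statistic = NA_real_)
    }
    tibble::tibble(year = year, measure = measure,
                   p_value = res$p_value, statistic = res$statistic)
  }) |> dplyr::bind_rows()
}

#' Paired at-transfer vs post-transfer laboratory comparisons
#'
#' For each year: the exact paired test for a change in the proportion
#' virologically suppressed, and the signed-rank test for a shift in CD4
#' count, both restricted to retained patients measured at transfer and at
#' the time point.
#'
#' @param patients Cohort tibble.
#' @param timepoints Output of [assess_timepoints()].
#' @param config An [analysis_config()].
#' @return A tibble: `year`, `outcome`, `n_pairs`, `p_value`, plus the
#'   paired proportions / medians behind each test.
#' @export
paired_lab_tests <- function(patients, timepoints,
                             config = analysis_config()) {
  tp <- timepoints |>
    dplyr::filter(.data$eligible, .data$retained) |>
    dplyr::inner_join(
      dplyr::select(patients, "patient_id", "vl_at_transfer",
                    "cd4_at_transfer"),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      supp_at_transfer = flag_outcomes(.data$vl_at_transfer, "hiv_rna",
                                       config)
    )
  purrr::map(sort(unique(tp$year)), function(y) {
    d <- tp[tp$year == y, ]
    vl <- d[!is.na(d$supp_at_transfer) & !is.na(d$vl_suppressed), ]
    cd4 <- d[!is.na(d$cd4_at_transfer) & !is.na(d$cd4_value), ]
    vl_test <- if (nrow(vl) > 0) {
      paired_proportion_test(vl$supp_at_transfer, vl$vl_suppressed)
    } else {
      list(p_value = NA_real_)
    }
    cd4_test <- if (nrow(cd4) > 0) {
      paired_median_test(cd4$cd4_at_transfer, cd4$cd4_value)
    } else {
      list(p_value = NA_real_)
    }
    dplyr::bind_rows(
      tibble::tibble(
        year = y, outcome = "vl_suppressed", n_pairs = nrow(vl),
        p_value = vl_test$p_value,
        pct_at_transfer = 100 * mean(vl$supp_at_transfer),
        pct_at_year = 100 * mean(vl$vl_suppressed),
        median_at_transfer = NA_real_, median_at_year = NA_real_
      ),
      tibble::tibble(
        year = y, outcome = "cd4_count", n_pairs = nrow(cd4),
        p_value = cd4_test$p_value,
        pct_at_transfer = NA_real_, pct_at_year = NA_real_,
        median_at_transfer = median(cd4$cd4_at_transfer),
        median_at_year = median(cd4$cd4_value)
      )
    )
  }) |> dplyr::bind_rows()
}

#' Run the full analysis and write the report files
#'
#' Runs [analyze_cohort()], the source-subset comparison, the baseline
#' table, the yearly outcome table with age-group tests, the paired
#' laboratory comparisons and the adjusted logistic model, and writes
#' `outcomes.csv` (per patient x year), `table1.csv`, `table2.csv`,
#' `table3.csv`, `figure2.csv`, `figure2_tests.csv`, `paired_tests.csv` and
#' `summary.json` to `out_dir`.
#'
#' @param patients,events,duplicates Analysis inputs (tibbles; `duplicates`
#'   may be `NULL`).
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return A list with every component, invisibly.
#' @export
build_report <- function(patients, events, duplicates = NULL,
                         config = analysis_config(), out_dir = NULL) {
  res <- analyze_cohort(patients, events, duplicates, config)
  if (!is.null(duplicates)) {
    events <- resolve_duplicates(events, duplicates)
  }
  transfers <- res$transfers
  timepoints <- res$timepoints
  table1 <- build_table1(patients, transfers, config)
  table3 <- compare_sources(patients, events, config)
  figure2 <- build_figure2(patients, transfers, timepoints, config)
  fig2_tests <- figure2_group_tests(figure2)
  paired <- paired_lab_tests(patients, timepoints, config)
  table2 <- tryCatch(fit_success_model(patients, transfers, config),
                     error = function(e) {
                       warn(paste0("logistic model not fitted: ",
                                   conditionMessage(e)))
                       NULL
                     })

  succ <- transfers[transfers$success, ]
  ci <- proportion_ci(nrow(succ), nrow(transfers))
  summary <- list(
    n_patients = nrow(transfers),
    n_success = nrow(succ),
    pct_success = ci$point,
    pct_success_ci = c(ci$lower, ci$upper),
    pct_within_18mo_of_success =
      100 * mean(succ$within_18_months),
    delay_from_transfer_median_iqr =
      unname(quantile(succ$delay_from_transfer_days, c(0.5, 0.25, 0.75),
                      na.rm = TRUE)),
    delay_from_last_contact_median_iqr =
      unname(quantile(succ$delay_from_last_contact_days,
                      c(0.5, 0.25, 0.75), na.rm = TRUE)),
    retention = lapply(sort(unique(figure2$year)), function(y) {
      r <- figure2[figure2$year == y & figure2$group == "all" &
                     figure2$measure == "retained", ]
      rci <- if (r$denominator > 0) {
        proportion_ci(r$numerator, r$denominator)
      } else {
        tibble::tibble(point = NA_real_, lower = NA_real_,
                       upper = NA_real_)
      }
      list(year = y, numerator = r$numerator, denominator = r$denominator,
           pct = rci$point, ci = c(rci$lower, rci$upper))
    })
  )

  out <- list(transfers = transfers, timepoints = timepoints,
              table1 = table1, table2 = table2, table3 = table3,
              figure2 = figure2, figure2_tests = fig2_tests,
              paired_tests = paired, summary = summary, config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(transfers, file.path(out_dir, "transfers.csv"))
    readr::write_csv(timepoints, file.path(out_dir, "outcomes.csv"))
    readr::write_csv(table1, file.path(out_dir, "table1.csv"))
    if (!is.null(table2)) {
      readr::write_csv(table2, file.path(out_dir, "table2.csv"))
    }
    readr::write_csv(table3, file.path(out_dir, "table3.csv"))
    readr::write_csv(figure2, file.path(out_dir, "figure2.csv"))
    readr::write_csv(fig2_tests, file.path(out_dir, "figure2_tests.csv"))
    readr::write_csv(paired, file.path(out_dir, "paired_tests.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Bar plot of yearly outcomes
#'
#' Convenience wrapper drawing the yearly retention / suppression / CD4
#' percentages as grouped bars.
#'
#' @param figure2 Output of [build_figure2()].
#' @param measures Which measures to draw.
#' @return A ggplot object.
#' @export
plot_outcomes <- function(figure2,
                          measures = c("retained",
                                       "vl_suppressed_of_assessed",
                                       "cd4_above_of_assessed")) {
  d <- figure2[figure2$measure %in% measures, ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$year), y = .data$pct,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "Years after successful transfer", y = "Per cent",
                  fill = "Age at transfer") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
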