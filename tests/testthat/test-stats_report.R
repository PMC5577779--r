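test_that("Clopper-Pearson intervals match direct binomial inversion", {
  expect_equal(proportion_ci(0, 10)$lower, 0)
  expect_equal(proportion_ci(10, 10)$upper, 100)
  # independent cross-check against stats::binom.test on a grid
  for (n in c(5, 17, 120)) {
    for (k in unique(c(0, 1, floor(n / 2), n))) {
      got <- proportion_ci(k, n)
      want <- 100 * binom.test(k, n)$conf.int
      expect_equal(c(got$lower, got$upper), as.numeric(want),
                   tolerance = 1e-12)
    }
  }
  ci <- proportion_ci(5, 10)
  expect_true(ci$lower < 50 && ci$upper > 50)
  expect_error(proportion_ci(3, 0), "n > 0")
  expect_error(proportion_ci(11, 10), "k <= n")
})

test_that("the paired proportion test is exact on discordant pairs", {
  expect_equal(paired_proportion_test(discordant = c(5, 5))$p_value, 1)
  expect_equal(paired_proportion_test(discordant = c(0, 8))$p_value,
               2 * 0.5^8)
  expect_equal(paired_proportion_test(discordant = c(8, 0))$p_value,
               2 * 0.5^8)
  # vector interface: discordant counts extracted from paired logicals
  x <- c(TRUE, TRUE, TRUE, FALSE, FALSE, NA)
  y <- c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE)
  res <- paired_proportion_test(x, y)
  expect_equal(res$discordant, c(2, 1))
  expect_equal(res$n_pairs, 5)
  expect_equal(res$p_value,
               paired_proportion_test(discordant = c(2, 1))$p_value)
  expect_equal(paired_proportion_test(discordant = c(0, 0))$p_value, 1)
})

test_that("signed-rank p-values match sign-assignment enumeration", {
  # oracle: enumerate all 2^n assignments of signs to |d|
  enum_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  }
  expect_equal(paired_median_test(c(0, 0, 0), c(1, 2, 3))$p_value, 0.25)
  expect_equal(enum_p(c(1, 2, 3)), 0.25)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:9, 1)
    d <- round(stats::rnorm(n, sd = 10), 3)
    d <- d[d != 0]
    if (anyDuplicated(abs(d))) next
    got <- paired_median_test(rep(0, length(d)), d)
    expect_equal(got$p_value, enum_p(d), tolerance = 1e-12)
    # cross-check against the standard exact implementation
    expect_equal(got$p_value,
                 stats::wilcox.test(d, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("signed-rank handles zeros and ties via the Pratt normal path", {
  expect_equal(paired_median_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # ties, no zeros: matches the tie-corrected normal approximation
  set.seed(8)
  x <- rep(0, 30)
  y <- sample(c(-3, -2, -1, 1, 2, 3, 4), 30, replace = TRUE)
  got <- paired_median_test(x, y, exact_max = 0)
  expect_equal(got$method, "pratt-normal")
  want <- stats::wilcox.test(y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(got$p_value, want, tolerance = 1e-10)
  # zeros present: statistic excludes zero ranks, p-value remains valid
  withz <- paired_median_test(rep(0, 10), c(0, 0, 0, 1, 2, -1, 3, 4, 5, 6))
  expect_equal(withz$method, "pratt-normal")
  expect_true(withz$p_value >= 0 && withz$p_value <= 1)
  expect_error(paired_median_test(NA, NA), "no complete pairs")
})

test_that("group comparison equals the hand-computed Pearson chi-square", {
  expect_equal(group_compare(10, 20, 15, 30)$p_value, 1)
  expect_equal(group_compare(10, 20, 10, 20)$statistic, 0)
  direct <- function(k1, n1, k2, n2) {
    o <- c(k1, n1 - k1, k2, n2 - k2)
    rs <- c(n1, n2); cs <- c(k1 + k2, n1 + n2 - k1 - k2)
    e <- c(rs[1] * cs[1], rs[1] * cs[2], rs[2] * cs[1], rs[2] * cs[2]) /
      (n1 + n2)
    stat <- sum((o - e)^2 / e)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  set.seed(12)
  for (i in 1:20) {
    n1 <- sample(10:50, 1); n2 <- sample(10:50, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    expect_equal(group_compare(k1, n1, k2, n2)$p_value,
                 direct(k1, n1, k2, n2), tolerance = 1e-12)
  }
  expect_warning(res <- group_compare(0, 10, 0, 10), "degenerate")
  expect_true(is.na(res$p_value))
})

# Builds a cohort + transfer table directly with success drawn from a
# logistic model, to test estimation against known coefficients.
simulate_logistic_cohort <- function(n, beta_suppressed = 0, beta0 = 1.4) {
  suppressed <- runif(n) < 0.75
  measured <- runif(n) < 0.95
  patients <- tibble::tibble(
    patient_id = sprintf("L%05d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    enrolment_date = as.Date("2000-01-01"),
    art_start_date = as.Date("2000-06-01"),
    age_at_enrolment = runif(n, 2, 16),
    age_at_art_start = 16.2,
    age_at_transfer = runif(n, 10, 19.9),
    transfer_out_date = as.Date("2010-01-01"),
    origin_facility = "ORIGIN",
    origin_level = sample(c("primary", "tertiary"), n, replace = TRUE),
    cd4_at_transfer = NA_real_,
    vl_at_transfer = ifelse(measured, ifelse(suppressed, 100, 10000),
                            NA_real_),
    cd4_at_art_start = NA_real_, cd4pct_at_art_start = NA_real_
  )
  patients$age_at_art_start <- pmin(16.2, patients$age_at_transfer - 0.1)
  patients$age_at_enrolment <- pmin(patients$age_at_enrolment,
                                    patients$age_at_art_start - 0.05)
  eta <- beta0 + beta_suppressed * suppressed
  success <- runif(n) < stats::plogis(eta)
  transfers <- tibble::tibble(patient_id = patients$patient_id,
                              success = success)
  list(patients = patients, transfers = transfers)
}

test_that("the adjusted model is near-null when covariates are noise", {
  set.seed(31)
  hits <- 0; total <- 0
  for (rep in 1:20) {
    sim <- simulate_logistic_cohort(2000)
    fit <- fit_success_model(sim$patients, sim$transfers)
    expect_equal(nrow(fit), 5)
    se <- (log(fit$ci_upper) - log(fit$ci_lower)) / (2 * stats::qnorm(0.975))
    within3 <- abs(log(fit$odds_ratio)) < 3 * se
    hits <- hits + sum(within3); total <- total + length(within3)
    expect_false(any(fit$separation))
  }
  expect_gte(hits / total, 0.99)
})

test_that("a true suppression effect of OR 2 is estimated and covered", {
  set.seed(47)
  reps <- 400
  res <- vapply(1:reps, function(rep) {
    sim <- simulate_logistic_cohort(5000, beta_suppressed = log(2),
                                    beta0 = 0.7)
    fit <- fit_success_model(sim$patients, sim$transfers)
    row <- fit[fit$term == "HIV-RNA <400 copies/ml at transfer", ]
    se <- (log(row$ci_upper) - log(row$ci_lower)) /
      (2 * stats::qnorm(0.975))
    c(covered = row$ci_lower <= 2 && 2 <= row$ci_upper,
      est = log(row$odds_ratio), se = se)
  }, c(covered = 0, est = 0, se = 0))
  # coverage can fall below nominal only by Monte-Carlo error
  mc_se <- sqrt(0.95 * 0.05 / reps)
  expect_gte(mean(res["covered", ]), 0.95 - 3 * mc_se)
  # the estimator is unbiased and its model SE matches the sampling SD
  expect_lt(abs(mean(res["est", ]) - log(2)),
            3 * stats::sd(res["est", ]) / sqrt(reps))
  expect_lt(abs(stats::sd(res["est", ]) / mean(res["se", ]) - 1), 0.15)
})

test_that("the model is complete-case on HIV-RNA at transfer", {
  set.seed(53)
  sim <- simulate_logistic_cohort(800)
  fit <- fit_success_model(sim$patients, sim$transfers)
  expect_equal(attr(fit, "n_used"),
               sum(!is.na(sim$patients$vl_at_transfer)))
})

one_patient_report <- function() {
  p <- make_patient(transfer_out_date = as.Date("2008-01-01"),
                    vl_at_transfer = 150, cd4_at_transfer = 700)
  link <- make_events("P1", "FAC-X", p$transfer_out_date + 30, "visit")
  s <- p$transfer_out_date + 30
  ev <- dplyr::bind_rows(
    link,
    make_events("P1", "FAC-X", s + 365, "visit"),
    make_events("P1", "FAC-X", s + 365 + 10, "lab", "hiv_rna", 80),
    make_events("P1", "FAC-X", s + 365 - 10, "lab", "cd4", 640)
  )
  list(patients = p, events = ev)
}

test_that("a single retained suppressed patient yields all-100% year 1", {
  d <- one_patient_report()
  res <- analyze_cohort(d$patients, d$events)
  fig <- build_figure2(d$patients, res$transfers, res$timepoints)
  y1 <- fig[fig$year == 1 & fig$group == "all", ]
  for (m in c("retained", "vl_measured", "vl_suppressed_of_assessed",
              "cd4_above_of_assessed")) {
    row <- y1[y1$measure == m, ]
    expect_equal(row$numerator, 1)
    expect_equal(row$denominator, 1)
    expect_equal(row$pct, 100)
  }
  expect_equal(y1$pct[y1$measure == "missing_vl"], 0)
})

test_that("figure-2 percentages partition and denominators shrink by year", {
  sim <- generate_cohort(cohort_gen_config(600, seed = 33))
  res <- analyze_cohort(sim$patients, sim$events, sim$duplicates)
  fig <- build_figure2(sim$patients, res$transfers, res$timepoints)
  all_rows <- fig[fig$group == "all", ]
  for (y in 1:3) {
    m <- function(meas, col = "numerator") {
      all_rows[[col]][all_rows$year == y & all_rows$measure == meas]
    }
    # measured + missing VL partition the retained
    expect_equal(m("vl_measured") + m("missing_vl"),
                 m("vl_measured", "denominator"))
    # age groups partition the cohort for every measure
    for (meas in unique(fig$measure)) {
      parts <- fig[fig$year == y & fig$measure == meas &
                     fig$group != "all", ]
      expect_equal(sum(parts$numerator),
                   all_rows$numerator[all_rows$year == y &
                                        all_rows$measure == meas])
    }
  }
  ret_den <- all_rows[all_rows$measure == "retained", ]
  expect_true(all(diff(ret_den$denominator[order(ret_den$year)]) <= 0))
  tests <- figure2_group_tests(fig)
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1, na.rm = TRUE))
})

test_that("the baseline table is recomputable and strata sum to the total", {
  sim <- generate_cohort(cohort_gen_config(300, seed = 35))
  res <- analyze_cohort(sim$patients, sim$events, sim$duplicates)
  t1 <- build_table1(sim$patients, res$transfers)
  n_row <- t1[t1$variable == "patients", ]
  expect_equal(sum(n_row$numerator[n_row$stratum != "all"]),
               n_row$numerator[n_row$stratum == "all"])
  cat_rows <- t1[!is.na(t1$pct), ]
  expect_equal(cat_rows$pct,
               100 * cat_rows$numerator / pmax(cat_rows$denominator, 1))
  sex <- t1[t1$variable == "sex" & t1$stratum == "all", ]
  expect_equal(sum(sex$numerator), nrow(sim$patients))
})

test_that("build_report writes a complete, parseable report", {
  sim <- generate_cohort(cohort_gen_config(400, seed = 39))
  dir <- withr::local_tempdir()
  rep <- build_report(sim$patients, sim$events, sim$duplicates,
                      out_dir = dir)
  for (f in c("transfers.csv", "outcomes.csv", "table1.csv", "table2.csv",
              "table3.csv", "figure2.csv", "figure2_tests.csv",
              "paired_tests.csv", "summary.json")) {
    expect_true(file.exists(file.path(dir, f)), info = f)
  }
  s <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(s$n_patients, nrow(sim$patients))
  expect_equal(s$pct_success, 100 * s$n_success / s$n_patients)
  paired <- rep$paired_tests
  ok <- !is.na(paired$p_value)
  expect_true(all(paired$p_value[ok] >= 0 & paired$p_value[ok] <= 1))
  p <- plot_outcomes(rep$figure2)
  expect_s3_class(p, "ggplot")
})
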