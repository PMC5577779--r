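#' Exact (Clopper-Pearson) binomial confidence interval for a percentage
#'
#' Inverts the binomial tail via beta quantiles: the lower bound is the
#' 2.5% quantile of Beta(k, n - k + 1) and the upper the 97.5% quantile of
#' Beta(k + 1, n - k), with the conventional endpoints at k = 0 and k = n.
#' Reported on the percentage scale.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `numerator`, `denominator`, `point`, `lower`,
#'   `upper` (per cent).
#' @export
#' @examples
#' proportion_ci(374, 460)  # 81.3% (77.4-84.8)
proportion_ci <- function(k, n, conf = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      n <= 0 || k < 0 || k > n) {
    abort("need 0 <= k <= n with n > 0")
  }
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  tibble::tibble(numerator = k, denominator = n,
                 point = 100 * k / n,
                 lower = 100 * lower, upper = 100 * upper)
}

#' Exact paired test for a change in a binary outcome
#'
#' Within-patient comparison of a binary state (e.g. virologic suppression)
#' at transfer versus a later time point, restricted to patients measured at
#' both. The exact McNemar construction: conditional on the number of
#' discordant pairs, the count discordant in one direction is Binomial(m,
#' 1/2) under the null, and the two-sided exact binomial p-value is
#' returned. With no discordant pairs the test is vacuous (p = 1).
#'
#' @param at_transfer,at_timepoint Logical vectors of equal length (pairs
#'   with any `NA` are dropped), or alternatively pass the discordant counts
#'   directly via `discordant`.
#' @param discordant Optional integer vector of length 2: the two discordant
#'   counts (only-at-transfer, only-at-timepoint).
#' @return A list with `p_value`, `n_pairs`, `discordant`.
#' @export
#' @examples
#' paired_proportion_test(discordant = c(0, 8))$p_value  # 2 * 0.5^8
paired_proportion_test <- function(at_transfer = NULL, at_timepoint = NULL,
                                   discordant = NULL) {
  if (is.null(discordant)) {
    ok <- !is.na(at_transfer) & !is.na(at_timepoint)
    x <- at_transfer[ok]; y <- at_timepoint[ok]
    discordant <- c(sum(x & !y), sum(!x & y))
    n_pairs <- length(x)
  } else {
    stopifnot(length(discordant) == 2, all(discordant >= 0))
    n_pairs <- NA_integer_
  }
  m <- sum(discordant)
  p <- if (m == 0) 1 else binom.test(discordant[1], m, 0.5)$p.value
  list(p_value = p, n_pairs = n_pairs, discordant = discordant)
}

#' Paired test for a shift in a continuous outcome (signed rank)
#'
#' Wilcoxon signed-rank test of paired values (e.g. CD4 at transfer versus a
#' later year), restricted to pairs with both values. With no zero
#' differences, no ties among absolute differences and at most `exact_max`
#' pairs, the exact null distribution of the positive-rank sum is used.
#' Otherwise a normal approximation with Pratt handling of zeros (zeros are
#' ranked with the rest, then their ranks discarded from the statistic and
#' the null moments) and the usual tie correction to the variance.
#'
#' @param x,y Paired numeric vectors; differences are `y - x`.
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return A list with `p_value`, `statistic` (positive-rank sum), `n`
#'   (non-missing pairs) and `method`.
#' @export
#' @examples
#' paired_median_test(c(0, 0, 0), c(1, 2, 3))$p_value  # 2/8
paired_median_test <- function(x, y, exact_max = 25) {
  ok <- !is.na(x) & !is.na(y)
  d <- y[ok] - x[ok]
  n <- length(d)
  if (n == 0) abort("no complete pairs")
  if (all(d == 0)) {
    return(list(p_value = 1, statistic = 0, n = n, method = "degenerate"))
  }
  has_zeros <- any(d == 0)
  nz <- d[d != 0]
  has_ties <- anyDuplicated(abs(nz)) > 0
  if (!has_zeros && !has_ties && n <= exact_max) {
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    p <- min(1, 2 * min(psignrank(v, n),
                        psignrank(v - 1, n, lower.tail = FALSE)))
    return(list(p_value = p, statistic = v, n = n, method = "exact"))
  }
  # Pratt: rank |d| including zeros, then drop zero ranks from both the
  # statistic and the null moments; tie correction on the variance.
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n0 <- sum(d == 0)
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(abs(nz))
  sigma2 <- (n * (n + 1) * (2 * n + 1) -
               n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  z <- (v - mu) / sqrt(sigma2)
  list(p_value = 2 * pnorm(-abs(z)), statistic = v, n = n,
       method = "pratt-normal")
}

#' Compare a binary outcome between two groups
#'
#' Pearson chi-square test on the 2x2 table of successes/failures by group,
#' without continuity correction (used to compare yearly outcomes between
#' the 10-14 and 15-19 age groups).
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @return A list with `p_value` and `statistic`; both `NA` (with a warning)
#'   when a margin of the table is zero.
#' @export
group_compare <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate 2x2 table; chi-square undefined")
    return(list(p_value = NA_real_, statistic = NA_real_))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(p_value = unname(ct$p.value), statistic = unname(ct$statistic))
}

#' Adjusted logistic model of successful transfer
#'
#' Maximum-likelihood logistic regression of transfer success on the five
#' a-priori covariates: sex (reference male), care level of the origin
#' facility (reference tertiary), virologic suppression at transfer
#' (reference not suppressed), the perinatal-infection proxy (enrolment
#' before the configured cutoff; reference enrolled at/after it), and age at
#' transfer — by default the binary 15-19 vs 10-14 contrast, optionally
#' continuous per-year (`age_coding = "continuous"`). Complete-case: patients
#' without an HIV-RNA at transfer are dropped. Wald 95% confidence intervals
#' and p-values. Covariates showing signs of separation (huge standard
#' errors on the log odds scale) are flagged rather than silently reported.
#'
#' @param patients Cohort tibble.
#' @param transfers Output of [classify_transfers()].
#' @param config An [analysis_config()].
#' @param age_coding `"binary"` (default) or `"continuous"`.
#' @return A tibble with one row per non-intercept term: `term`,
#'   `reference`, `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`,
#'   `separation`; attribute `n_used` gives the complete-case count.
#' @export
fit_success_model <- function(patients, transfers,
                              config = analysis_config(),
                              age_coding = c("binary", "continuous")) {
  age_coding <- match.arg(age_coding)
  df <- patients |>
    dplyr::inner_join(dplyr::select(transfers, "patient_id", "success"),
                      by = "patient_id") |>
    dplyr::mutate(
      female = .data$sex == "female",
      primary_care = .data$origin_level == "primary",
      suppressed_at_transfer = flag_outcomes(.data$vl_at_transfer,
                                             "hiv_rna", config),
      perinatal = .data$age_at_enrolment < config$perinatal_cutoff_years,
      older = .data$age_at_transfer >= config$adolescent_age_split_years
    ) |>
    dplyr::filter(!is.na(.data$suppressed_at_transfer))
  if (nrow(df) < 10) abort("too few complete cases to fit the model")

  terms <- c(female = "female", primary_care = "primary_care",
             suppressed_at_transfer = "suppressed_at_transfer",
             perinatal = "perinatal",
             age = if (age_coding == "binary") "older" else "age_at_transfer")
  fml <- stats::reformulate(unname(terms), response = "success")
  fit <- glm(fml, data = df, family = binomial())
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]

  labels <- c(
    femaleTRUE = "Female sex",
    primary_careTRUE = "Primary care origin",
    suppressed_at_transferTRUE = "HIV-RNA <400 copies/ml at transfer",
    perinatalTRUE = "Likely perinatal infection",
    olderTRUE = "Age at transfer 15-19 years",
    age_at_transfer = "Age at transfer (per year)"
  )
  refs <- c(
    femaleTRUE = "male",
    primary_careTRUE = "tertiary care",
    suppressed_at_transferTRUE = ">=400 copies/ml",
    perinatalTRUE = "enrolled at/after cutoff",
    olderTRUE = "10-14 years",
    age_at_transfer = "-"
  )
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  out <- tibble::tibble(
    term = unname(labels[rownames(sm)]),
    reference = unname(refs[rownames(sm)]),
    odds_ratio = exp(est),
    ci_lower = exp(est - stats::qnorm(0.975) * se),
    ci_upper = exp(est + stats::qnorm(0.975) * se),
    p_value = sm[, "Pr(>|z|)"],
    separation = se > 5 | abs(est) > 10
  )
  if (any(out$separation)) {
    warn(paste0("possible separation for: ",
                paste(out$term[out$separation], collapse = "; ")))
  }
  attr(out, "n_used") <- nrow(df)
  out
}
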