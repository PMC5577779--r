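---
title: "Linkage-based ascertainment of post-transfer outcomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage-based ascertainment of post-transfer outcomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortlink)
```

## The problem

Adolescents on antiretroviral therapy frequently transfer between health
facilities — most often from specialist paediatric (tertiary) care down to
primary care in early adolescence. From the originating cohort's point of
view their follow-up is censored at transfer, so the questions that matter
— did they reach a new facility, how quickly, were they retained, did they
stay virologically suppressed — cannot be answered from clinic data alone.
Where a health system uses a single patient identifier across all services,
those questions become answerable by deterministic linkage: pull every
visit, laboratory and pharmacy record carrying the patient's identifier and
look for activity at facilities other than the origin after the transfer-out
date.

`cohortlink` implements that ascertainment as a reusable pipeline. Its
inputs are a cohort table of transferred patients, per-source event streams,
and an alias map for patients erroneously holding more than one identifier.
Its outputs are per-patient transfer outcomes, per-patient-per-year windowed
assessments, a source-sensitivity table, and the descriptive and inferential
summaries an analyst would publish.

## Outcome definitions

**Successful transfer.** Any record (visit, laboratory test or pharmacy
dispensing) at a facility other than the origin facility, dated strictly
after the transfer-out date. We read "after" as strict because a same-day
record at another facility is plausibly an administrative contact arranged
before the patient actually moved; `strict_after_transfer = FALSE` gives
the inclusive reading. The linkage event is the earliest qualifying record;
date ties break by source priority visit < lab < pharmacy (a visit is the
strongest evidence of physical presence), then lexicographically by
facility so results are order-independent.

**Transfer delay.** Two definitions are maintained: days from the
transfer-out date to the linkage event, and days from the last contact at
the origin facility on or before transfer-out. The second is the one used
in the source-comparison table; its anchor is computed from the events
visible to the active source subset so each row of that table is internally
consistent, and falls back to the transfer-out date when the subset captures
no origin contact (making the two definitions coincide there).

**Retention at year t.** At least one *visit* within the closed window of
±183 days around the successful-transfer date plus 365·t days. Only
patients with at least t + 0.5 years between successful transfer and
database closure are assessable; all denominators exclude the ineligible.
By default a visit back at the origin facility does not count — the
quantity of interest is engagement at the new site — but
`retention_counts_origin = TRUE` gives the "any facility" reading, since
the underlying administrative definition is genuinely ambiguous.

**Windowed laboratory outcomes.** For each year, the HIV-RNA and CD4
measurements minimising the absolute distance to the time point within the
same ±183-day window; an equidistant pair resolves to the earlier
measurement (reflecting the state carried forward from the previous year).
Suppression is HIV-RNA < 400 copies/ml, strictly; the CD4 flag is
strictly > 500 cells/µl by default (`cd4_strict = FALSE` gives ≥, the
convention sometimes used in descriptive tables).

**Missing year-3 HIV-RNA.** Retained patients without a year-3 measurement
are categorised in priority order: a suppressed measurement within 183 days
after the window closes (`later_suppressed`); otherwise a fully suppressed
post-transfer history with at least one value (`previously_continuously_
suppressed`); otherwise an unsuppressed later value (`later_unsuppressed`);
otherwise `no_evidence`. This mirrors how clinicians argue that a missing
test in a stable patient is unlikely to hide failure.

All date arithmetic is in integer days: 6 months = 183 days, 18 months =
548 days, a nominal year = 365 days, and fractional years of potential
follow-up use 365.25 days/year. None of these conversions is canonical;
they are configuration fields of `analysis_config()`.

## The synthetic cohort generator

No patient-level extract of this kind can be published, so the package
ships a generator whose defaults encode the study conditions the pipeline
is designed for: 53.3% female, 72.2% transferring at 10–14 years, 79.3%
from tertiary facilities, transfer-out dates uniform over March 2004 –
December 2014, database closure 2016-10-15. Five per cent of transfers
leave the observed system entirely (emitting no post-transfer events —
observationally indistinguishable from never linking, which is exactly the
ambiguity the real analysis faces); 85% of the remainder link to a new
facility.

The transfer delay is log-normal with median 56 days and
σ = ln(134/27)/(2·Φ⁻¹(0.75)) ≈ 1.19, chosen so the quartiles sit at 27 and
134 days — the log-scale asymmetry of a median-56, IQR-27–134 summary is
what a log-normal reproduces. The draw is truncated at each patient's
remaining observation time: a "successful" transfer in the generator means
the patient is actually observed at the new site before closure, which
keeps the latent truth table and the observable data mutually consistent.
Note the truncation point is at least 654 days for every patient, so the
median is essentially unaffected. This delay model implies ~97% of linkages
occur within 18 months; empirically reported values are nearer 95%,
indicating a real-world tail heavier than log-normal — a known limitation,
not a calibration target.

After linkage, visit occasions recur with exponential gaps (mean 84 days)
until attrition (exponential, 5%/year hazard). Pharmacy dispensings occur
only on visit dates. Yearly HIV-RNA/CD4 measurements occur with
completeness declining from 89%/87% at year 1 to 80%/72% at year 3
(measured values are suppressed with probability 0.80, i.i.d. by default; a
first-order Markov option with persistence 0.9 exists, since routine data
give no within-patient correlation to match). Patients who skip the year-3
HIV-RNA receive one shortly after the window with probability 0.4,
emulating the observation that most such patients test late rather than
never. Each occurring contact is captured into its stream with per-source
probability (visits 0.95, labs 0.85, pharmacy 0.55 — dispensing systems
were not electronic everywhere). Two per cent of linked patients have their
post-transfer events recorded under a second identifier, with the alias
pair published in the duplicate map. Unlinked in-scope patients bounce back
to the origin facility with probability 0.3, exercising the rule that
origin-facility activity never counts as successful transfer.

The attrition hazard and visit frequency are not quantities the study
reports; the defaults are chosen once as plausible for a stable
ART-programme population and land retention in the 85–95% range over three
years. They are configuration, not claims.

**What passing tests show — and don't.** Parameter-recovery tests show the
pipeline inverts *this* generating process: with full capture it reproduces
the latent truth exactly, and with realistic capture it recovers the
generative proportions within binomial error. Real extracts differ in ways
the generator does not emulate: facility-level (not per-contact) coverage
gaps, clustered visit schedules, migration, mortality, and silent
transfers. Results on synthetic data validate the logic of the
ascertainment, not the accuracy of any particular real-world estimate.

## Statistical components

- **Proportions** get exact Clopper–Pearson 95% intervals (beta-quantile
  inversion of the binomial tails). Normal-approximation intervals are
  visibly different at the sample sizes involved (e.g. they do not
  reproduce a 77% lower bound for 374/460), and exact intervals are the
  long-standing default of the statistical packages used for such analyses.
- **Paired binary comparisons** (suppression at transfer vs. at year t,
  limited to patients measured at both) use the exact McNemar construction:
  a two-sided exact binomial test at p = ½ on the discordant counts.
- **Paired continuous comparisons** (CD4) use the Wilcoxon signed-rank
  test: the exact null distribution when there are no zeros or ties and
  n ≤ 25, otherwise a normal approximation with Pratt handling of zero
  differences and the standard tie correction. Zeros are informative of "no
  change", which is why Pratt (rank-then-discard) is preferred to silently
  dropping them.
- **Group contrasts** (10–14 vs. 15–19 at transfer) use Pearson chi-square
  without continuity correction on the 2×2 table.
- **The adjusted model** is a maximum-likelihood logistic regression of
  success on five a-priori covariates: sex, origin care level, suppression
  at transfer, the perinatal proxy (enrolment before 13 years; 10 as a
  sensitivity cutoff), and age group at transfer. Age is a binary 15–19 vs.
  10–14 contrast by default; a per-year continuous coding is available
  (`age_coding = "continuous"`), because published versions of such models
  sometimes report effect sizes (e.g. an OR with a very tight CI) that are
  only plausible per year of age. Complete-case on the at-transfer HIV-RNA;
  Wald intervals; covariates with degenerate standard errors are flagged as
  possible separation rather than silently printed.

## Numerical and degenerate-input choices

- Windows are closed at both ends; boundary measurements and visits count.
- A patient with no events at all is an unsuccessful transfer, not an
  error; a source subset capturing no events yields a 0% row with an absent
  delay summary.
- Duplicate maps are resolved to transitive closure; chains resolve with a
  warning, cycles are a configuration error. Resolution is idempotent and
  preserves the event multiset.
- All classification is invariant to row order of the inputs.
- Zero discordant pairs give p = 1; an all-zero difference vector gives
  p = 1; degenerate 2×2 margins give `NA` with a warning.

## Problem sizes

The test suite exercises the classifier against brute-force oracles on
1000+ randomised small event sets, recovers generative parameters on
5000-patient cohorts, and checks interval coverage over 1000 seeded draws
and estimator calibration over 400 model replicates of n = 5000 — sizes at
which binomial standard errors are small enough for the assertions to have
power, chosen as the package's own test design. The acceptance script
regenerates a 5000-patient cohort and recomputes every headline quantity
from scratch.

## Known limitations

- Linkage is deterministic on the shared identifier; probabilistic linkage
  on names or demographics is out of scope.
- Mortality is not modelled or linked, so non-retention conflates death,
  disengagement and undetected movement.
- Silent transfers (patients resuming care elsewhere without transfer
  documentation) are invisible by construction: only patients with a
  documented transfer-out enter the cohort table.
- The generator's per-contact capture model understates the bimodality of
  real coverage gaps (whole facilities lacking electronic dispensing), so
  the synthetic source-comparison table reproduces the qualitative ordering
  of ascertainment by source, not the magnitudes a real extract shows.
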