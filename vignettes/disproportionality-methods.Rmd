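---
title: "Methods: multi-database disproportionality analysis of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-database disproportionality analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems (FAERS in the United States, the Canada
Vigilance Adverse Reaction database, JADER in Japan) collect voluntarily
submitted suspicions that a drug caused an adverse event. They have no
denominator of exposed patients, so incidence cannot be estimated; what can
be estimated is *disproportionality* — whether an event is reported for a
drug more often than the reporting pattern of all other drugs would
predict. `pvsignal` implements that analysis for a cohort defined by an
indication (here, ovarian / fallopian-tube / primary-peritoneal cancer) and
an adverse-event class defined by a narrow standardized MedDRA query (here,
interstitial lung disease, ILD), across three database dialects and their
pooled union.

The licensed MedDRA dictionary cannot be redistributed, so the narrow ILD
term set ships as an editable text file
(`system.file("extdata", "smq_ild_narrow.txt", package = "pvsignal")`) that
users with a MedDRA licence should replace with the official narrow-query
term list. The drug vocabulary (13 study drugs with trade-name synonyms) is
likewise a plain CSV.

## The report model and cohort construction

All dialects are harmonized into one tibble-backed model with one row per
(report, drug) pair: demographics, country, event date, verbatim and
canonical drug name, role (primary suspect / secondary suspect /
concomitant / interacting), indication, a set of event Preferred Terms,
seriousness with its criteria, and outcome. FAERS-like ages arrive with a
unit code (YR/DEC/MON/WK/DY) and are converted to years; unknown units
become missing rather than guessed.

Cohort construction applies, in order:

1. **Primary-suspect restriction.** Ovarian-cancer regimens are multi-drug;
   counting concomitant mentions would dilute attribution, so only the
   reporter-designated primary suspect contributes.
2. **Indication filter.** Case-insensitive substring matching of the
   report's indication against a configurable term list. Free-text
   substring matching (rather than exact PT matching) is a deliberate
   choice: indication fields in these databases mix coded and verbatim
   text, and the cohort definition ("ovarian cancer" and close variants)
   is robust to that. Reports with a missing indication are excluded and
   counted, mirroring the exclusion of unclear indications.
3. **Single-drug attribution.** A report left with two or more *distinct*
   primary-suspect drugs after filtering is excluded entirely (and
   counted). The alternative — letting one report increment cell *a* for
   several drugs — would double-count events; exclusion is conservative
   and affects few reports.
4. **Event flagging.** `ild_flag` is true when any event term matches the
   SMQ, case-insensitively after whitespace normalization.

Filters only select and annotate; they never modify surviving field
values, and the test suite asserts this invariant.

### Deduplication

Within a database, rows sharing a report identifier are duplicate
submissions of one case. "Most complete" needs a metric, and we use the
count of non-missing fields among age, weight, country, event date,
seriousness, outcome and indication, with ties broken by the latest event
date and then by the lexicographically last source row (so the choice is
deterministic for byte-identical inputs).

Across databases the same case can be filed separately (e.g. a Japanese
case in both FAERS and JADER). Rows agreeing exactly on (age rounded to
whole years, canonical drug, event date, country) — all four non-missing —
and spanning more than one database are collapsed to a single record, with
the FAERS-like record retained (it carries the richest field set; CVAR-like
is preferred over JADER-like when FAERS is absent). Requiring all four key
fields guards against false merges: records with a missing key are never
collapsed. Both passes are idempotent and order-preserving.

Per-database signal tables are computed on within-database-deduplicated
cohorts; the combined table on the cross-database-deduplicated union.

## Signal statistics

For each drug, within a report universe of size N = a+b+c+d:

* `PRR = (a/(a+c)) / (b/(b+d))`, with 95% CI
  `exp(ln PRR ± 1.96·sqrt(1/a − 1/(a+c) + 1/b − 1/(b+d)))`;
* `ROR = ad/bc`, with 95% CI
  `exp(ln ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`;
* Pearson chi-square and its Yates continuity-corrected variant — both are
  always computed. The *uncorrected* statistic is the default for
  reporting and for signal criterion 1, because published signal tables in
  this field (including the study this package reproduces) are consistent
  with the Pearson form even when the Yates formula is quoted;
* the Bayesian information component `IC = log2((a+0.5)/(a_exp+0.5))`,
  `a_exp = (a+b)(a+c)/N`, whose +0.5 shrinkage stabilizes small counts,
  with the lower credibility bound approximation
  `IC025 = IC − 3.3(a+0.5)^(−1/2) − 2(a+0.5)^(−3/2)`.

Conventions fixed throughout: natural logarithms inside both Wald CIs with
z = 1.96; full-precision values internally with 2-decimal *half-up*
rounding for display (`round_half_up()`), matching how such tables are
printed; no pseudo-count (Haldane) correction — a zero cell marks the
point estimates and CIs undefined, the chi-square and IC (which tolerate
zero cells) are still reported, and undefined estimates make their signal
criterion false, so a drug with no cases is "no signal" rather than an
error.

The three-criterion rule (cases ≥ 3 with PRR ≥ 2 and χ² ≥ 4; ROR CI lower
bound > 1; IC025 > 0) is combined with `ANY` by default — the common
practice, and the sense in which a drug whose PRR is below 2 can still be a
signal via the ROR and IC criteria — with `ALL` available for stricter
screening.

Age stratification splits at 65 years (boundary in the upper stratum);
reports without age are excluded from both strata and counted. Stratum
cell counts partition the age-known universe exactly, which the tests
assert as an invariant.

## Comparative analyses

**Fatality.** Death constituent ratios are deaths over outcome-known
reports (missing and UNKNOWN outcomes leave the denominator). The
ILD-vs-non-ILD mortality contrast is a Pearson chi-square (no continuity
correction) on the death × ILD 2×2 table.

**Pairwise regimen comparison.** With a single binary regressor, logistic
regression of event on drug membership has a closed form: the Wald odds
ratio from the two (a, c) pairs. The matrix entry at (row i, column j) is
`(a_j·c_i)/(a_i·c_j)` — the event odds of the column drug relative to the
row drug — with CI `exp(ln OR ± 1.96·sqrt(1/a_i + 1/c_i + 1/a_j + 1/c_j))`
and a Wald-z two-sided p. We use the counts form rather than an iterative
fit because they coincide exactly here; the published pairwise matrix
reproduces from the pooled cells to 2 decimals. Bonferroni family size is
the number of off-diagonal pairs (upper triangle), and reciprocity
(`OR[i,j]·OR[j,i] = 1`, unit diagonal) is checked on every run.

**Volcano statistics.** Per drug, a two-sided conditional Fisher exact
test on (a, b, c, d), Bonferroni-adjusted over the number of drugs in the
universe. Two-sided Fisher has competing definitions; we fix the
*minimum-likelihood* convention — sum the probabilities of all tables with
the observed margins whose point probability does not exceed the observed
one, within a 1e-7 relative tolerance guarding floating-point ties. The
test suite checks this against an independent enumeration built from
binomial coefficients for every table with N ≤ 40, and against
`stats::fisher.test` on random tables. Coordinates are ln(ROR) against
−log10 of the adjusted p (floored at 1e-300); undefined-ROR drugs are
emitted flagged, without coordinates.

**Severity.** Ordered outcome severity is compared between two groups by
the proportional-odds model `logit P(Y ≤ k | x) = θ_k − β·x`, whose
`exp(β)` is the odds of the x = 1 group occupying a more severe category.
The outcome ordering is RECOVERED < RECOVERING < RECOVERED_WITH_SEQUELAE <
NOT_RECOVERED < DEATH by default — the coding is not universal, so it is
an explicit, configurable argument. The fit is a Newton ascent on the
analytic gradient with step halving, convergence at gradient norm < 1e-8
within 100 iterations, observed-information Wald CI, and explicit
non-estimable flagging for single-category data and complete separation
(disjoint category ranges, or |β| > 30). Categories empty in both groups
are dropped first; the estimate is invariant to that merge (tested). The
implementation is cross-checked against `MASS::polr` and a profile-
likelihood grid search.

## The synthetic-data generator

The generator emulates the *statistical structure the analysis assumes*:
each report independently samples a drug from a configured mixture, an
event flag from the drug's conditional event probability (baseline for
non-study drugs), one SMQ term if flagged else one background term,
demographics and an event date, an indication from a mixture containing
both eligible and ineligible strings, an outcome, and then per-field
missingness. Duplicates are injected explicitly: within-database
duplicates as degraded copies sharing the report identifier (so the
completeness rule must recover the original), cross-database duplicates as
re-filed FAERS-like records with fresh identifiers but identical key
fields. Every injection is ledgered, and the generator also records
coincidental cross-database key collisions so deduplication can be checked
for *exactness*, not merely plausibility.

Defaults are fixed once to emulate the study conditions at a workable
scale: database sizes 30,000 / 4,000 / 2,000 (preserving the roughly
15:2:1 proportions of the real extracts), equal weight across the 13 study
drugs, event probabilities spanning the observed range of associations
(clear positive signals for the ADC and one PARP inhibitor, null and
inverse associations elsewhere, baseline 2%), FAERS-like missingness
rates, 1% duplicate injection, and a severity log-odds shift of +1.2 for
the ADC. The severity shift is implemented by exponential tilting of the
cumulative odds — exactly the proportional-odds alternative the
comparative module fits, which makes parameter recovery a meaningful
test. The closed-form true ROR implied by a configuration
(`expected_ror()`) is the event odds under the drug against the event odds
under the renormalized complement mixture.

Randomness comes from R's Mersenne-Twister stream seeded once per
generation; the seed is recorded in every output's provenance and in the
ground-truth ledger, and byte-identical regeneration from the same seed is
tested.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: correlated multi-drug regimens,
time-varying reporting (the Weber effect), country- or reporter-dependent
reporting propensities, coding drift across MedDRA versions, and
dose/duration fields. Recovery of configured RORs shows the estimator and
pipeline are correct under the model's own assumptions, not that real
spontaneous-report biases are absent.

## Validation study sizes

The packaged validation studies use problem sizes chosen to make the
relevant asymptotics visible while keeping the suite quick to run:
CI-coverage and parameter-recovery studies use 200 replicates of 50,000
reports (coverage pooled over drug × replicate checks, asserted at ≥ 93%);
the null-calibration study uses 2,002 drug-replicates at 20,000 reports
each (the one-sided ROR-CI criterion should fire at about 2.5%); the
Fisher oracle comparison enumerates all 135,750 tables with N ≤ 40; the
2×2 null-interval study uses 2,000 multinomial replicates.

## Known limitations

* Wald intervals for PRR/ROR are first-order; at very small counts their
  coverage degrades, which is the usual argument for leaning on IC025 in
  sparse strata.
* The IC025 formula is the standard closed-form approximation to the
  2.5th posterior percentile, not a full BCPNN posterior; other shrinkage
  estimators (EBGM/MGPS) are out of scope.
* Cross-database deduplication can only merge records whose four key
  fields are complete and exactly equal; near-duplicates (age off by a
  year, date off by a day) are not merged, matching the conservative
  published procedure.
* The pipeline is deterministic; the configured seed exists for
  provenance and for downstream resampling, not because any analysis step
  is stochastic.
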