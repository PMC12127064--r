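---
title: "Scoring the ITQ with clinical checks: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the ITQ with clinical checks: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itqcc)
```

## The measurement problem

The International Trauma Questionnaire (ITQ) is an 18-item self-report
measure of the ICD-11 diagnoses of posttraumatic stress disorder (PTSD) and
complex PTSD (CPTSD). Each of the six symptom clusters — re-experiencing in
the here and now (Re), avoidance (Av) and sense of threat (Th) for PTSD;
affective dysregulation (AD), negative self-concept (NSC) and disturbed
relationships (DR) for the "disturbances in self-organization" (DSO) side —
is measured by two items, and each scale adds three functional-impairment
items. Items are rated 0-4; a rating of 2 ("Moderately") or higher counts
the symptom as present.

Self-report items often produce higher endorsement rates than clinical
interviews because a short item cannot always convey the clinical meaning,
intensity or duration that makes an experience a symptom. *Clinical checks*
address this: each item gets one yes/no follow-up question, shown only when
the item is endorsed (score ≥ 2), that probes exactly that clinical
element; answering "no" withdraws the endorsement. The gated instrument is
the ITQ-CC. Two items — numbing (`dso_ad2`) and feeling cut off from others
(`dso_dr1`) — trialled two checks each; the pre-set rule retains, per item,
the check with the larger observed decrease in endorsement
(`select_check_variant()`, ties to the lower variant id), which selected
variant 1 for numbing and variant 2 for cut-off. Those are the defaults of
`itq_mode(gated = TRUE)`.

## The diagnostic algorithm

`itq_diagnose()` applies the ICD-11 rules: a cluster is met when at least
one of its two items is endorsed; an impairment block when at least one of
its three items is endorsed. The PTSD block is Re ∧ Av ∧ Th ∧ PTSD
impairment; the DSO block is AD ∧ NSC ∧ DR ∧ DSO impairment. CPTSD requires
both blocks, PTSD requires the PTSD block without the full DSO block, and
everything else — including DSO criteria alone, for which ICD-11 defines no
diagnosis — is `none`. The labels are mutually exclusive by construction.

Gating is one-directional at the item level, so items, clusters, the
impairment blocks, the CPTSD label and the either-disorder indicator are
all monotone non-increasing under checks. The PTSD *label* is the
exception: a respondent meeting CPTSD whose DSO endorsements fail their
checks while the PTSD ones survive migrates from CPTSD to PTSD, so gated
PTSD counts can rise. This is why the package reports both discordant
counts `b` and `c` for the disorder table and why the verify harness
refuses to reconstruct a Z statistic for the PTSD row from marginal counts
alone.

Three behaviours were genuinely open and are decided as follows:

* **Impairment checks.** The gating mechanics are defined per item; we
  apply one check per impairment item, aggregated by the same any-of-three
  rule, rather than a single check per block. This is the reading
  consistent with "one check per item" and it keeps the scoring engine
  uniform.
* **Exposure precondition.** Diagnosis does not require a reported
  traumatic event by default (`require_exposure = FALSE`), so prevalence
  denominators are the full cohort; the filter is available as a mode
  flag for sensitivity analyses.
* **Missing item scores.** `missing = "strict"` (default) refuses to score
  incomplete records; `missing = "lenient"` scores missing as 0 and
  records the imputation count in an attribute. Forced-completion surveys
  have no missing data, so strict is the safe default.

## The paired statistics

All evaluation statistics live in small plain-value functions.

**Relative decrease.** `percentage_decrease(E, CC)` returns
`100·(E − CC)/E`. Following the reporting convention of the published
summary tables, the pipeline computes it from the percentages *as printed*
(one decimal, half-up) rather than from raw counts; the two differ by up to
a few tenths of a point (e.g. nightmares: 101/247 = 40.9% from counts
vs 40.7% from 25.3 and 15.0). `build_report(..., basis = "count")` provides
the count-based variant.

**McNemar's Z.** For paired proportions with discordant counts `b` and
`c`, the uncorrected statistic is `(b − c)/√(b + c)` and the
continuity-corrected one `(|b − c| − 1)/√(b + c)`, floored at zero; both
with two-sided normal p-values. For a monotone predicate `c = 0`, so the
uncorrected statistic is exactly `√b`. The published analysis used the
uncorrected form at the symptom and cluster levels and the corrected form
at the disorder level; `mcnemar_z()` therefore takes an explicit
`corrected` flag, and `build_report()` applies that mixed policy (stated in
its documentation) so its tables are comparable with the published ones.
The corrected normal p-value agrees with the exact binomial McNemar test
to within 0.01 once `b + c ≥ 40`, the regime all the published tests are
in; the tests check this against `stats::binom.test()` and the statistic
identity against `stats::mcnemar.test()`.

**Reliability and planning.** `cronbach_alpha()` is the standard
`k/(k−1)·(1 − Σ item var / total var)`. `required_sample_size(p, conf, E)`
is the normal-approximation prevalence-survey formula
`⌈z² p(1−p)/E²⌉`. For the planning case of a 5% prevalence with 99%
confidence and a 2% margin it returns **788** (2.5758² · 0.0475 / 0.0004);
survey reports sometimes print slightly different values from proprietary
calculators (782 has been reported for this exact case), which the
function intentionally does not reproduce — it computes, it does not quote.

## The verify harness

Respondent-level data for the ITQ-CC evaluation survey were never
released, but every headline derived quantity is an exact function of the
printed table cells. `itq_reference_tables()` ships those cells (counts
and percentages for 12 symptom items — the two dual-variant items under
both checks — 2 impairment blocks, 6 clusters and 3 disorder rows, N =
975) as plain CSVs, and `itq_verify()` recomputes every derived column:
percentages from counts, decrease counts, decrease percentages from the
printed percentages, and Z from the counts under the level-appropriate
correction. Two printed cells fail verification, and are flagged rather
than matched:

* the hyperalert decrease count is printed 41 where 320 − 179 = 141 (and
  √141 = 11.87 matches the printed Z, identifying 41 as the typo);
* the either-disorder baseline is printed 14.9% where 146/975 rounds to
  15.0% (the decrease formula consumes the printed 14.9, which is what
  reproduces the printed 41.6%).

## The synthetic cohort generator

No respondent-level data exist to test the pipeline against, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes. The model, chosen as the minimal one that yields
correlated PTSD/DSO symptom profiles, both diagnoses, and a measurable
false-positive stratum:

1. **Exposure.** A lifetime trauma-event count: zero with probability
   0.275, otherwise 1 + a negative-binomial draw (mean 4.09, size 1.35),
   spread uniformly over the 21 ITEM event slots. This reproduces the
   survey's 72.5% exposed and mean 3.69 events (SD ≈ 4.0); it does *not*
   attempt the survey's event-by-event frequencies, which are
   study-specific marginals, not model content.
2. **Traits.** Bivariate standard-normal PTSD/DSO severities with
   correlation `rho = 0.84`, each shifted by `0.35·log(1 + events)`.
3. **Items.** Propensity = trait + per-item shift + N(0, 0.66²); the
   Likert score is the number of global cutpoints (0.40, 1.15, 1.95, 2.75)
   below the propensity, graded-response style.
4. **Truth status.** An endorsement whose propensity clears the
   endorsement cutpoint by at least `fp_width = 0.35` is a *true symptom*;
   one in the band just above it is a *false positive* — the construct the
   checks exist to remove. This is one admissible mechanism for "no"
   answers among several (nothing is known about why real respondents
   failed checks); it is an assumption of the generator, not an inference.
5. **Checks.** "Yes" with probability `pass_true = 0.95` for true symptoms
   and `pass_false = 0.15` for false positives, independently across items
   given truth status (no shared careless-responder factor; none would be
   identifiable). The dual-variant items draw both checks with per-variant
   false-positive pass rates reflecting their differing stringency.

The defaults were calibrated once, at large n, to the survey's marginal
structure and then frozen: ungated symptom-item endorsement rates of
24-36%, impairment blocks near 27-29%, check-induced item decreases of
about 28-36%, ungated prevalence near 6.6% PTSD / 11% CPTSD (survey: 5.4 /
9.5), and an either-disorder relative decrease near 39% (survey: 41.6%).
The conjunction of eight correlated requirements is where this
two-factor model is coarsest — it slightly over-produces diagnoses
relative to the survey at matched item marginals — so cohort-level tests
use calibration *bands* (e.g. ungated CPTSD in 7-12%, item decreases in
15-50%) rather than point targets. Passing them shows the pipeline's
arithmetic and monotonicity behave correctly on realistically structured
data; it does not validate the generator as a model of any real
population, and real data will differ in ways the generator deliberately
omits (careless responding, item-specific check quality, demographic
heterogeneity).

`recover_check_params()` closes the loop: pooling the 16 single-check
items, the proportion of "yes" answers among true and false-positive
endorsements recovers `pass_true` and `pass_false` to within three
binomial standard errors at n = 20,000.

## Numerical conventions and problem sizes

Percentages are reported to 1 decimal and Z to 2 decimals, rounded half
away from zero (`round_half_up()`; base `round()` half-to-even would turn
e.g. 10.045 into 10.04). Degenerate inputs fail loudly: `mcnemar_z()` with
no discordant pairs, `percentage_decrease()` on a zero baseline and
`cronbach_alpha()` on a zero-variance total all raise errors, while
`build_report()` records an `NA` Z for no-discordance rows so an
all-confirming cohort still reports. Fixed seeds make every simulation —
including the CSV files a cohort writes to — byte-reproducible.

The shipped tests run exhaustive enumerations where the space is small
(all 5² score pairs × check combinations per cluster; all 5³ × 2³
impairment configurations) and simulations sized to their purpose:
100,000 respondents for exposure marginals, 50,000 for dose-response in
`pass_false`, 20,000 for parameter recovery, 10,000 for cohort calibration
bands, and a few thousand for monotonicity sweeps. The whole suite
completes in well under a minute.

## Limitations

The generator is a convenience model, not an empirical claim; its
false-positive mechanism is unverifiable from the published record. The
verify harness can confirm only quantities that are functions of printed
cells — scale reliabilities (α = 0.88/0.90), per-event exposure
frequencies and the disorder-level PTSD Z (whose `b` and `c` are not
recoverable from marginals) cannot be recomputed from the published record
and are covered only by property tests on synthetic data.
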