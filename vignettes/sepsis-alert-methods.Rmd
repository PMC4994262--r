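---
title: "Methods: probabilistic sepsis alerting with informatively missing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic sepsis alerting with informatively missing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisalert)
```

## The problem and the model

Screening for severe sepsis and septic shock in the first hour of an
emergency-department encounter must work with whatever has been charted by
then: vital signs are almost always present (≥ 95 %), but laboratory values
are mostly absent, and absence is informative — clinicians order a white
blood cell count in roughly 53 % of septic encounters versus 22 % of the
rest, and lactate in 36 % versus 3 %. Imputation is both awkward and
biased here, because the missingness mechanism is tied to the outcome.

`sepsisalert` therefore uses a Gaussian naïve Bayes classifier. Each
modeled feature carries a mean and standard deviation per class, estimated
by `nb_fit()` from the non-missing values of that feature within each
class, and the posterior of `nb_score()` multiplies class-conditional
Gaussian densities over the **observed** features only. Skipping a missing
feature multiplies both class likelihoods by nothing, so the posterior for
an encounter with no observed features is exactly the class prior. The
prior defaults to the training prevalence and can be overridden.

Assumptions worth stating plainly:

- **Class-conditional independence.** Features are treated as independent
  given the class. Vital signs and labs are of course correlated; naïve
  Bayes tolerates this for ranking purposes but its posteriors are then
  miscalibrated, which is why an alert threshold on the posterior scale
  (such as the conventional 0.05) is an operating point to be tuned, not a
  probability to be interpreted. No calibration correction is applied.
- **Gaussian likelihoods on the raw scale.** No discretization or
  transformation is performed. Binary 0/1 columns are accepted if
  explicitly configured but sit poorly under a Gaussian density; they are
  excluded from the default feature sets.
- **Missing-at-random within class.** Estimation from observed values per
  class is unbiased when, within a class, the decision to measure is
  independent of the value. Severity-linked ordering *within* the septic
  class would bias class parameters toward sicker patients; modeling that
  is out of scope.

Numerical choices: the posterior is computed in log space (log prior odds
plus per-feature log density ratios, mapped back through `plogis`), which
is algebraically identical to the direct product but immune to underflow at
many features; the tests verify agreement with a naïve direct-product
implementation to 10⁻¹⁰. Every fitted SD is floored at `sd_floor`
(default 10⁻⁶ in feature units) so a constant column cannot produce a
degenerate density.

## Feature selection

`forward_select()` reconstructs forward stepwise selection driven by
bootstrap out-of-bag AUC: for a candidate set, each bootstrap replicate
fits the model on the in-bag resample and computes the concordance AUC on
the rows never drawn; the candidate with the best mean out-of-bag AUC is
accepted if it improves on the current set by at least `improvement_tol`.
Details the procedure's published description leaves open, and the choices
made here:

- **Replicates** `n_bootstrap = 200` by default — enough for stable means
  at interactive scale; the selection-behavior tests use 100.
- **Stopping rule**: minimum mean-AUC gain `improvement_tol = 0.002`, plus
  an optional `max_features` cap. The empty-set baseline AUC is 0.5.
- **Stratification** (default on): resampling within each class. With a
  0.38 % outcome an unstratified in-bag draw would frequently contain no
  septic encounters at small n.
- **Degenerate replicates**: an out-of-bag set lacking a class, or an
  in-bag sample leaving a low-availability feature with < 2 observed
  values in a class, is redrawn (≤ 10 retries) rather than scored, keeping
  every per-replicate AUC defined.
- **Clinician preference** is formalized as rank-based tie-breaking: when
  candidates lie within `equivalence_band` (default 0.005) of the step's
  best mean AUC, the highest-ranked name in `preference_order` wins. This
  is the closest testable reading of letting preference decide among
  parameters of statistically equivalent utility.
- **Paired comparisons**: all candidates at a step share the same bootstrap
  replicates (a common derived seed), a standard variance-reduction device
  when comparing candidates.

Two five-feature modeled sets are packaged (`default_feature_set()`):
`"abstract"` (mean BP, temperature, age, heart rate, WBC — the default)
and `"results"` (temperature, heart rate, respiratory rate, WBC, mean
arterial pressure). The source material lists both without reconciling
them; the package takes no position on which was deployed and ships both.

## Alert evaluation

`auc_continuous()` is the Mann–Whitney concordance (ties ½) computed from
midranks; it equals the trapezoidal area under the empirical ROC curve,
and the tests hold the two routes together to 10⁻¹². For a
single-threshold binary alert the ROC has one interior vertex, so its AUC
is (sensitivity + specificity)/2 (`binary_auc()`).

Conventions, fixed once and used everywhere:

- Alerts fire at score **≥** threshold (ties alert).
- Candidate thresholds are the unique observed scores plus +∞; no
  interpolation. The searches are exact binary-search enumerations over
  these candidates: `threshold_for_sensitivity()` returns the *largest*
  cutpoint meeting the sensitivity target, `threshold_for_fp_budget()` the
  *smallest* cutpoint whose false-positive burden fits the alerts/day
  budget, `threshold_max_binary_auc()` breaks ties toward the higher
  threshold (fewer alerts).
- Study duration is 456 days (April 2009 through June 2010 inclusive);
  this reconciles the published FP/day column with FPR × 93,421 within
  printed rounding, and `study_calendar()` carries the per-month day
  counts.
- The coefficient of variation uses the sample SD (n − 1 denominator) —
  verified to reproduce the published 16.72 % monthly sepsis-rate CV from
  the monthly counts.
- Report rounding in printed comparisons: percentages to 1 decimal, AUC to
  3 decimals.
- The "SIRS-derived" comparator is implemented as a configurable k-of-4
  rule over temperature, heart rate, respiratory rate and WBC, with
  missing components unsatisfied. Its published operating point (FPR
  0.4 %) is far stricter than any plain ≥ 2-of-4 rule, so the original
  rule evidently had additional conjuncts; no default k is claimed to
  reproduce it.

`monthly_performance()` reports a month with a single outcome class as
`NA` for AUC and sensitivity and excludes it from that metric's CV, rather
than fabricating a value.

## The synthetic cohort generator

`simulate_cohort()` exists so every stage is testable without data access.
Its defaults (`default_cohort_config()`) encode the published summary
tables carried in `printed_tables()`:

- **Families**: the published evidence per feature is a median and
  quartiles. Right-skewed positive features (age, heart rate, WBC,
  lactate) use a lognormal — the visible skew (septic WBC quartiles
  9.8–20.6 around a median of 14.3) rules out symmetry — while
  temperature and the pressures use a normal. `calibrate_spec()` maps
  (median, q25, q75) to location and scale in closed form using the exact
  quartile constant 2·Φ⁻¹(0.75) ≈ 1.349; a two-parameter family pins the
  median and the interquartile spread (for the lognormal, the quartile
  *ratio*).
- **Clamps**: age ≥ 14 years (the cohort's inclusion criterion),
  temperature 30–43 °C, lactate ≥ 0. Clamping truncates ~3 % of the
  non-septic age tail; all other clamps are many SDs out.
- **Respiratory rate** has no published distribution but the SIRS
  comparator and one of the candidate feature sets need it; it ships with
  clearly synthetic defaults (non-septic N(16, 3²), septic N(24, 6²),
  availability 95 %/97 %).
- **Missingness** is class-conditional Bernoulli with the published
  availabilities — missing-at-random within class, by design matching the
  estimator's assumption. Severity-linked ordering is deliberately not
  emulated.
- **Mean BP** is recomputed as (SBP + 2·DBP)/3 wherever both parents are
  observed, and drawn from its own calibrated marginal otherwise.
- **Labels**: exact per-month counts in calendar mode (the packaged
  15-month calendar reproduces 93,773 encounters and 352 septic exactly),
  Bernoulli(0.0038) in pooled mode.
- **Concurrent screens**: both published triage indicators are generated;
  the nurse identification flag (sensitivity 54.3 %, FPR 3.1 %) is the
  comparator used in incremental-true-positive accounting, matching the
  published comparator row.
- **Dependence**: `class_correlation` shares a one-factor Gaussian copula
  across features within class; the default 0 gives class-conditional
  independence, the generator analogue of the classifier's assumption.
- **Determinism**: one integer seed, one generator stream, a documented
  draw order (labels, then each feature in configuration order, then sex,
  screen, flag); the same configuration yields a byte-identical table.

What the generator does **not** emulate — and therefore what passing tests
do and do not show: real vitals/labs correlate within class, missingness is
plausibly severity-linked, distributions drift over months, and the real
candidate pool had ~75 variables. A pipeline that is correct on this
generator is correct as software and as arithmetic; the generator
reproduces published *marginals*, not the joint distribution, so
discrimination on synthetic replays (continuous AUC ≈ 0.96–0.98 across
seeds) brackets rather than reproduces the published 0.953, and the tests
treat [0.88, 0.99] as a plausibility band, not a point target.

## Test design and problem sizes

The suite pairs every nontrivial computation with an independent oracle:
concordance vs trapezoidal ROC integration (and `pROC` as a third route),
log-space posterior vs direct Bayes products, threshold searches vs
exhaustive enumeration, stepwise selection vs the closed-form binormal AUC
Φ(d/√2).

Statistical checks are sized so their tolerances are meaningful. Marginal
and parameter-recovery checks run on case-enriched draws (prevalence 0.5
with unchanged class-conditional marginals): at the study prevalence a
50,000-encounter cohort holds only ~190 septic encounters, where the
sampling error of a class SD (~5 %) exceeds the 2 % recovery tolerance —
the check would measure seed luck, not estimator quality. The binding case
is the WBC SD: a lognormal's sample SD carries excess-kurtosis-inflated
error of roughly √((2+κₑ)/4n), so the recovery check uses 400,000
encounters, putting the 2 % band at ≥ 3.9 sampling SEs for every
feature-class with availability ≥ 20 %. Mean BP is excluded from moment
recovery because its generative law is the parent composition, not its own
marginal. Selection-behavior checks use 2,000-encounter balanced cohorts
and 100 bootstrap replicates across 20 seeds; the end-to-end replay runs
the full 93,773-encounter calendar. The whole suite runs in about a
minute.

## Known limitations

- Naïve Bayes posteriors are miscalibrated under correlated features;
  thresholds are operating points, not probabilities.
- The generator's marginal-only calibration means synthetic operating
  points (e.g., sensitivity at a fixed posterior threshold) are not
  comparable to published ones; only threshold-*search* behavior and
  burden arithmetic are.
- The published quantile column headed "20 %" is interpreted as the 25th
  percentile, following the table footnote that states median and
  quartiles.
- The packaged transcription preserves two typographic oddities of the
  source tables (an inconsistent incremental-true-positive cell in the
  SIRS row, one nurse monthly AUC inconsistent with its own sensitivity
  and FPR); both are recorded in the fixture notes and excluded from
  arithmetic audits.
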