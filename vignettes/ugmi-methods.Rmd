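---
title: "Methods: the uGMI, CGM metric suite, and biomarker comparison pipeline"
author: "ugmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the uGMI, CGM metric suite, and biomarker comparison pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugmir)
```

## The problem

Laboratory HbA1c is the established biomarker of chronic glycemic exposure
and of microvascular complication risk in type 1 diabetes, but it is
confounded by between-person variation in glycation and red-cell turnover
(the *glycation gap*).  Continuous glucose monitoring (CGM) measures the
glucose exposure directly.  The **updated glucose management indicator
(uGMI)** maps mean sensor glucose (AG) to the HbA1c that the measured
glucose would produce at glycation steady state, so an individual's
laboratory HbA1c and their uGMI differ by exactly the glycation-gap and
assay components.  `ugmir` implements the uGMI, the consensus CGM metric
suite, a synthetic case-control cohort generator with an explicit glycation
gap, and the statistical pipeline used to compare glycemic biomarkers
against a binary complication outcome such as incident diabetic
retinopathy.

## The uGMI and unit systems

The uGMI is a reciprocal-form (Michaelis-Menten-like saturation) curve in
AG, derived from steady-state glycation kinetics (glycation rate constant
3.4e-7 l/mmol/day, red-cell removal rate 0.0095/day, Michaelis constant
8514 mmol/l; these are carried as metadata by `kinetic_constants()` — the
closed form is authoritative):

$$\mathrm{uGMI}\ (\mathrm{mmol/mol}) = \frac{1}{0.07808/\mathrm{AG}_{\mathrm{mmol/l}} + 0.003889} - 23.497$$

$$\mathrm{uGMI}\ (\%) = \frac{1}{15.36/\mathrm{AG}_{\mathrm{mg/dl}} + 0.0425}$$

The two parameterizations describe one curve on the two HbA1c reporting
scales.  The affine master equation linking the scales is taken as
NGSP(%) = 0.0915 × IFCC(mmol/mol) + 2.15 — this rounding, rather than the
five-digit variant, is the one under which the NGSP-form constants convert
*exactly* to the printed IFCC-form constants
(`ugmi_constants_from_ngsp()`), which is also how the package proves the
two forms coherent: `formula_coherence()` evaluates both forms over an AG
grid and reports the maximum absolute discrepancy (< 0.01 mmol/mol over
3-25 mmol/l, driven purely by the printed rounding).  The glucose factor is
fixed at 18.0 mg/dl per mmol/l, the value consistent with the same
algebra.  We treat the IFCC form as primary and the NGSP form as the
derived parameterization.

The function is strictly increasing and concave in AG with supremum
1/0.003889 − 23.497 ≈ 233.6 mmol/mol; inputs must be strictly positive.
The linear comparator GMI (`gmi_comparator()`) defaults to the widely
published regression GMI(%) = 3.31 + 0.02392 × AG(mg/dl); its coefficients
are configurable because published pairs vary by data source, and nothing
in the package asserts its values against study-specific numbers.

Display rounding follows clinical convention: NGSP to one decimal place,
IFCC to the nearest integer (`round_hba1c()`).

## CGM metrics and participant aggregation

A `cgm_trace()` is canonicalized on construction: sorted, de-duplicated
(first occurrence wins, which also resolves daylight-saving duplicates;
all timestamps are treated as timezone-naive clock times), and readings
outside the physiologic sensor range 0.5-45 mmol/l are dropped with a
message.  The metric suite (`summarize_trace()`) is:

* **AG** — arithmetic mean; **SD** — sample (n−1) standard deviation;
  **CV** = 100·SD/AG.
* **TIR** (3.9-10 mmol/l) and **TITR** (3.9-7.8) as *closed* intervals;
  **TAR** (> 10) and **TBR** (< 3.9) strict — so TBR + TIR + TAR = 100
  exactly for every trace.  This boundary convention is forced by
  requiring an exact partition; band percentages are reading-count based,
  appropriate for near-uniform 5-minute sampling (duration weighting is
  out of scope).
* **uGMI** of AG and the comparator GMI.
* **wear percentage** — readings observed relative to the count expected
  at the nominal interval over the window (or the observed span when no
  window is given).

Windows are half-open: `window_trace(trace, anchor, days)` keeps
`anchor − days ≤ t < anchor` with the anchor taken at midnight, and a
reading stamped exactly at the anchor midnight is excluded.  The same
half-open convention is used for diagnosis-date censoring.

`sufficiency_filter()` screens windows for CGM completeness with the
consensus defaults — at least 70% wear over at least 14 days — because
study descriptions of "incomplete CGM data" rarely state a threshold;
both values are configurable.

`participant_aggregate()` produces one feature row per participant.  For
cases, visits dated on or after the diagnosis date are discarded; the
HbA1c feature is the mean of the remaining visits' laboratory values; CGM
features are computed by **pooling** the readings of the remaining visits'
sufficient windows (a per-visit-mean mode is available behind a switch).
Pooling is visit-window based: a window attached to a discarded
post-diagnosis visit contributes nothing, and a final guard drops any
reading on or after the diagnosis date.  This keeps the retained windows
whole, so with zero glycation noise the aggregated HbA1c agrees with the
uGMI of the pooled AG to well under 0.2 mmol/mol (the residual is
window-vs-pool weighting plus wear-thinning noise at 5-minute sampling).

## The synthetic cohort generator

No participant-level dataset accompanies the analysis the package
implements, so `simulate_cohort()` generates case-control cohorts with the
statistical structure the pipeline assumes.  Design:

* **Traces.**  Per participant, glucose follows an exactly discretized
  Ornstein-Uhlenbeck process around a chronic setpoint (mean-reversion
  time 2 h) plus a 24-hour sinusoid, thinned by a per-participant wear
  probability (uniform on 0.75-0.98) and clipped to the sensor range.
  This is the simplest trace model reproducing first and second moments
  and short-range autocorrelation; meal excursions are deliberately not
  modelled — variability targets are set directly through the stationary
  SD.
* **Population.**  Setpoints are normal with mean 9.63 and SD 1.7 mmol/l;
  stationary SDs normal with mean 3.2 and SD 1.0 mmol/l (CV around
  25-45%, the range typical of type 1 diabetes).  The SD spread is chosen
  wide so that variability metrics (SD, CV, and partly the band metrics)
  decouple from mean glycemia across participants — cohorts of this kind
  show variability carrying far less outcome information than mean
  glucose, and the generator reproduces that profile.
* **Outcome.**  P(case) = plogis(−4.836 + 0.474 × setpoint).  The
  coefficients were calibrated once, by numerical integration against the
  setpoint prior, so that the expected case and control mean glucose are
  10.3 and 9.1 mmol/l at an overall prevalence of 71/161 — the group
  contrast typical of incident-retinopathy case-control cohorts.  The
  implied within-group SDs (≈1.6 mmol/l) and the implied quintile risk
  gradient (≈20% in the lowest to ≈70% in the highest uGMI quintile)
  follow from the same calibration.  Cases receive a diagnosis date
  uniform in the final year of a 3-year horizon (emulating a median
  follow-up near 2.8 years), and post-diagnosis visits are simulated so
  censoring is exercised.
* **HbA1c link.**  Each visit's laboratory HbA1c is
  uGMI(true window AG) + per-participant glycation offset + assay noise.
  The offset is additive on the IFCC scale with SD 6 mmol/mol — the
  simplest model that makes HbA1c carry no more outcome information than
  the uGMI, with a spread consistent with published glycation-gap/HGI
  distributions (0.5-0.8% NGSP) and with the ≈12 mmol/mol HbA1c SDs such
  cohorts report.  Assay SD is 1.5 mmol/mol.  Increasing the offset SD
  degrades HbA1c's association with the outcome while leaving the uGMI's
  unchanged in expectation — the glycation-gap mechanism the pipeline is
  designed to expose.
* **Visits.**  2-5 per participant, scheduled with at least a 91-day gap
  so 90-day windows never overlap; cohort assembly rejection-samples
  participants until the target counts (71 cases, 90 analyzable controls)
  are met exactly, discarding cases with no pre-diagnosis visit.  A single
  integer seed fixes the entire dataset.

**What the generator does not emulate**: physiologic insulin-glucose
dynamics, meal and exercise excursions, device-specific noise, drifting
setpoints, comorbidity covariates, and any correlation between the
glycation gap and the outcome.  Consequently, passing recovery tests shows
the pipeline detects the modelled mechanism — not that real data behave
this way.

### A note on per-replicate rank stability

With 161 participants and five-bin discretization, a plug-in mutual
information score has sampling noise of roughly 0.02 nats — the same order
as the true gaps separating the uGMI from the band metrics under the
calibrated effect sizes.  The *expected* ordering (uGMI above HbA1c above
variability metrics) is recovered, but the argmax over nine correlated,
noisy scores is not stable in every replicate.  The acceptance suite
measures exactly this per-replicate stability over 20 seeded cohorts and
reports the observed rates; the generator was calibrated to the cohort
moments above and was not adjusted afterward to force those rates.

## The association pipeline

* **Discretization** (`quantile_bin()`): equal-frequency bins, k = 5 by
  default (consistent with quintile-based risk reporting), sizes differing
  by at most one (larger bins first), ties broken by stable (value, row
  index) order.  A constant feature collapses to one bin with a warning.
* **MIS** (`mutual_info()`, `mis_ranking()`): plug-in mutual information
  in nats from the empirical contingency table of the binned feature
  against the outcome.  Rows are per participant by default (per-visit
  analysis is possible by building the feature table per visit).
* **mRMR** (`mrmr_rank()`): greedy, *difference* form — relevance minus
  mean redundancy against already-selected features — chosen because its
  scores are signed: a negative score marks a feature as predominantly
  redundant, which is the interpretation the pipeline reports.
* **RFE** (`rfe_rank()`): recursive elimination under a random forest,
  dropping the lowest mean-decrease-in-Gini feature, with stratified
  cross-validated accuracy recorded at each subset size.
* **ROC** (`roc_auc()`): threshold sweep over unique scores classifying
  positive when score > t, trapezoid integration; with ties this equals
  the rank-sum concordance with ties counted 1/2.  Risk direction is
  "higher is positive"; `auc_ranking()` flips protective metrics
  (TIR/TITR/TBR) automatically by the sign of the point-biserial
  correlation and reports the flip.
* **Cumulative-rate curves** (`cumulative_rate_curves()`): accuracy, TPR
  and FPR versus threshold, satisfying
  accuracy = prevalence·TPR + (1−prevalence)·(1−FPR) identically.
* **Quintile risk tables** (`quintile_risk_table()`): per-bin mean metric
  (IFCC, and NGSP rounded to 1 d.p.), outcome rate, 1st-vs-4th and
  2nd-vs-3rd comparisons by two-sided Fisher exact test by default (a
  z-test option exists; the table records which was used), and the rate
  increase per 1% NGSP computed from the 1-d.p. NGSP means and rounded to
  the nearest integer.
* **Fixed-threshold trees** (`threshold_tree()`): no threshold learning;
  the clinical target 53 mmol/mol (7.0% NGSP) is the default.  The
  two-layer tree splits on uGMI then HbA1c, and the induced classifier
  calls a participant positive only when every split variable exceeds its
  threshold; per-node totals, class counts and leaf majorities are
  reported so all metrics can be recomputed from the structure.
* **Model comparison** (`model_comparison()`): logistic regression versus
  random forest on uGMI, HbA1c, and both; stratified 5-fold
  cross-validation with 4 repeats; forest nodesize tuned on a small grid
  by out-of-bag error inside training folds only; pairwise accuracy
  differences tested by a seeded sign-flip permutation (10,000 draws) over
  per-prediction correctness indicators.

## Reproducibility and problem sizes

Every stochastic stage consumes a single seeded RNG stream, so one seed
reproduces a whole simulation-plus-analysis bundle byte for byte;
`run_end_to_end()` writes the resolved configuration (unknown keys are
rejected at configuration time) alongside the outputs.  The test suite
exercises full-size cohorts (161 participants, 90-day windows at 5-minute
sampling) for the recovery experiments — 20 seeded replicates — and
smaller hourly-sampled cohorts for structural and round-trip checks; the
exhaustive mutual-information cross-check enumerates all 2×2 tables with
cell counts up to 6 and all 3×2 tables with counts up to 4, sampling
larger shapes randomly.

## Limitations

* The uGMI's kinetic constants are taken as given; personalized glycation
  kinetics and red-cell lifespan modelling are out of scope.
* Band metrics are reading-count based; duration weighting for irregular
  sampling is not implemented.
* The generator's higher moments and autocorrelation are stated modelling
  choices, not estimates from any particular cohort.
* Quintile p-values depend on the test chosen; the package defaults to
  Fisher's exact test and labels its output accordingly.
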