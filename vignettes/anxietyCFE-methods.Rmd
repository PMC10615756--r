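---
title: "Convergent functional evidence scoring for anxiety biomarkers: methods"
author: "anxietyCFE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergent functional evidence scoring for anxiety biomarkers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the scoring
model and its assumptions, the parameters that matter, what the
synthetic-data generator emulates (and does not), and the numerical
choices the implementation makes.

# The model

## Phenotype and state labels

Each subject contributes one or more visits. Momentary anxiety is the
SAS-4 score (4-item visual analog scale, 0–100); the STAI-State subscale
(20–80) marks clinical severity. `labelState()` assigns each visit a
deterministic label:

* **LOW** — SAS-4 ≤ 40
* **SEVERE** — SAS-4 ≥ 60 *and* STAI-State ≥ 55
* **HIGH** — SAS-4 ≥ 60 (without concordant STAI severity)
* **INTERMEDIATE** — otherwise

A SEVERE visit is by construction also a high-anxiety visit; wherever the
pipeline needs a two-pole contrast (diametric pairing, reference groups)
SEVERE sits on the HIGH pole. This is a package decision: the thresholds
only define SEVERE as a refinement of HIGH, and treating it otherwise
would discard the most informative visits.

## Normalization

Expression arrives array-normalized (e.g. RMA) on a log2-like scale. The
only transformation the package applies is per-probeset z-scoring within
**gender × primary-diagnosis strata** (`zscoreByStratum()`), which removes
the two dominant demographic sources of expression variability before
arms are compared. Sample standard deviations use the n−1 denominator;
zero-variance cells become 0 with a warning; a stratum of one sample is
an error rather than a silent NaN.

Crucially, the validation arm is normalized with the *discovery arm's
frozen parameters* (stored in `zscoreParams()`): validation is an
out-of-sample test, and re-estimating means and SDs on the validation arm
would leak its distribution into the comparison. The independent test arm
is z-scored on its own parameters, as a cohort analyzed de novo would be.

## Step 1 — within-subject discovery

`findDiametricPairs()` collects consecutive visit pairs of one subject
whose labels flip between LOW and HIGH/SEVERE. Only consecutive pairs
count: non-adjacent flips straddle unobserved state changes.

For each probeset and pair, `pairConcordance()` asks whether the probeset
tracked the state change in a consistent direction, by either of two
analyses:

* **DE** — the expression difference across the pair exceeds
  `de_fold_threshold` (default 0.263 ≈ 1.2-fold on log2 scale) in a
  consistent direction;
* **AP** — the Absent/Present detection call flips with the state.

`discoveryScore()` converts the percentage of concordant pairs into
points with inclusive cuts: ≥ 33% → 2, ≥ 50% → 4, ≥ 80% → 6. The
probeset's *direction* ("increased"/"decreased" in high anxiety) is the
sign of the summed pair differences; the better-scoring of DE and AP is
kept per probeset.

The within-subject design is the core assumption: each subject is their
own control, so stable between-subject differences (ancestry, medication,
chronic illness) cancel and only state-tracking variation scores.

## Step 2 — Convergent Functional Genomics

`cfgScore()` aggregates curated literature evidence per gene over six
categories — {human, animal} × {genetic, brain expression, peripheral
expression} — capping each category at 2 points and the total at 12. The
evidence table is an *input*: the package does not curate literature.
Candidates must reach discovery + CFG ≥ 6 (`selectCandidates()`), so a
probeset can survive on strong internal evidence, strong external
evidence, or a mixture.

## Step 3 — validation in severe anxiety

For each candidate, three visit-level groups are formed: the discovery
arm's LOW visits, its HIGH (including SEVERE) visits, and the validation
arm's SEVERE visits. Scoring (`scoreValidation()`):

* 2 points if group means are **stepwise** — strictly ordered
  low < high < severe in the discovery direction;
* 2 more if a one-way fixed-effects ANOVA across the three groups is
  nominally significant (p < 0.05);
* 2 more if it survives Bonferroni over the number of candidates tested.

The units of analysis are *visits*, not subject means: the severe arm
contributes one visit per subject by design, and collapsing the discovery
arm to subject means would average away the within-subject contrast that
step 1 selected for.

## Step 4 — predictive testing

In the independent test arm, each candidate is evaluated against four
targets (`testPrediction()`):

* **state_sas4**, **state_stai** — ROC AUC for classifying high-anxiety
  visits. The AUC is computed by the rank-sum (Mann–Whitney) identity
  with ties counted one half; its p-value is the one-sided Wilcoxon test
  in the candidate's discovery direction.
* **hosp_first_year** — AUC for hospitalization within one year of the
  visit.
* **hosp_all_future** — Cox proportional-hazards ratio per 1 SD of
  expression for time to first future hospitalization, oriented in the
  discovery direction.

Each target is tested in the whole cohort (ALL), per gender, and per
gender × diagnosis stratum (with SZ and SZA additionally pooled as
PSYCHOSIS), both cross-sectionally (visit values) and longitudinally
(subject-level slope/mean features, `longitudinalFeatures()`). Per
target, `step4Points()` awards max(3 if significant in ALL, 2 if in a
gender stratum, 1 if in a gender × diagnosis stratum) — the *maximum*
rule, not a sum, so a marker cannot stack points for the same signal
re-observed in nested strata; broader generalization simply earns more.

## Composite scores

`cfe3Score()` = discovery + CFG + validation (cap 24; panel gate ≥ 8 —
one third of the cap). `cfe4Score()` adds the four step-4 categories
(cap 36). `selectTopPanel()` takes the gate survivors and
`panelAggregate()` predicts from a panel as the direction-aligned mean
z-score.

## Clinician report

`clinicianReport()` digitizes each panel biomarker against reference
group averages (`referenceThresholds()`): at or beyond the high-group
mean (in the marker's direction) → 1, between the group means → 0.5,
at or beyond the low-group mean → 0; mirrored for decreased markers.
Risk percentile = 100 × mean digitized score. Drug matching
(`drugMatchPercentile()`) credits a drug for each marker scoring ≥ 0.5
that it modulates *opposite* to its high-anxiety direction, normalized by
the number of markers scoring ≥ 0.5. The chronic-risk percentile is the
mean of the first-year and all-future hospitalization percentiles — the
simplest symmetric combination, chosen because the source material prints
both components but does not define the combination.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `low`, `high` (SAS-4) | 40, 60 | score points | published diametric thresholds |
| `severe_stai` | 55 | STAI points | published severity criterion |
| `de_fold_threshold` | 0.263 | log2 expression | ≈1.2-fold; exposed because the published DE call threshold is not recoverable |
| discovery cuts | 33/50/80% | % concordant pairs | published 2/4/6-point cuts, inclusive |
| CFG caps | 2 / category, 12 total | points | published scheme |
| candidate gate | ≥ 6 | points | published combined cutoff |
| validation `alpha` | 0.05 | — | nominal significance; Bonferroni divides by n candidates |
| step-4 `alpha` | 0.05 | — | nominal; `bonferroniFlag()` reports the stricter tier separately |
| CFE3 gate | ≥ 8 | points | one third of the 24-point cap |

Simulation parameters (`cohortSimConfig()`): arm sizes (60/40/200
subjects), 2–5 visits per subject ~3–6 months apart, `state_effect` 1.0
SD, `severe_extra_effect` 0.5 SD, `noise_sd` 1.0, `trait_log_hazard`
log(2) per SD of trait score, `baseline_hazard` 0.08 events/year,
detection threshold 6 on a baseline of N(6, 1). Effects of ~1 noise SD
give planted markers per-pair concordance around the 80% cut — strong but
not trivial, so recovery tests exercise the scoring margins.

# What the generator emulates — and what it does not

The generator plants truth so every stage can be tested by recovery:

* a **discovery arm** whose visits alternate LOW/HIGH, guaranteeing
  diametric pairs for every subject;
* a **validation arm** of single severe visits (SAS-4 ≥ 62, STAI ≥ 55);
* a **test arm** with mixed states and exponential
  time-to-hospitalization whose log-hazard is `trait_log_hazard` × the
  subject's direction-aligned mean trait-marker z-score;
* gender × diagnosis strata allocated by largest remainder, with later
  arms restricted to strata the discovery arm populates (so frozen
  normalization parameters always cover them);
* **state markers** that shift with the visit label, **trait markers**
  that carry a stable subject-level liability, and detection calls
  thresholded on expression.

It deliberately does *not* emulate: probe-level noise and normalization
artifacts; correlated co-expression modules (planted markers are
independent given the phenotype); medication, batch, ancestry or
circadian structure; informative dropout (censoring is independent);
many-to-one probeset–gene mappings; or missing phenotypes. Passing
recovery tests therefore shows the *scoring machinery* is correct and
well-powered under its own assumptions — it does not show the biomarkers
themselves generalize, and no synthetic result should be read as evidence
about real cohorts. The published headline cohort statistics cannot be
reproduced at all, because the underlying clinical data was never
deposited; the test suite instead verifies the arithmetic of every
published score that *is* recomputable from printed component cells.

# Numerical choices

* **AUC** is exact rank arithmetic (ties one half), verified against a
  brute-force all-pairs oracle on 1,000 random instances; p-values use
  the normal-approximation Wilcoxon test (`exact = FALSE`) uniformly, so
  tied and untied data follow one code path.
* **ANOVA** is `stats::oneway.test(var.equal = TRUE)` — the classical
  fixed-effects F test.
* **Cox** models (`survival::coxph`) standardize the predictor
  internally, so ratios are per 1 SD; non-converged fits are flagged, not
  silently kept. AUC tests require ≥ 2 visits per class and Cox ≥ 3
  events in a stratum; smaller strata return NA rather than unstable
  estimates.
* **Stepwise ordering is strict** (<, not ≤): a flat profile is not
  evidence of ordering.
* **Reproducibility**: all stochastic code is seed-driven; identical
  configurations produce byte-identical pipeline outputs.
* **Test problem sizes** (the package's own choice for a fast default
  suite): most property tests use 20/12/60-subject arms with 300
  probesets; distributional checks (binormal AUC closed form, hazard
  monotonicity, end-to-end recovery) use 120–500-probeset arrays and
  150–500 observations, sizes at which the tested expectation exceeds
  its Monte-Carlo error by a comfortable margin. Tolerances are stated
  per test (e.g. AUC vs closed form ±0.02, hazard-ratio recovery
  [1.7, 2.3] at n = 500) and derive from the statistic's sampling error
  at that size, not from observed outcomes.

# Limitations

Beyond the generator's idealizations above: the CFG step inherits any
bias of its curated evidence table; probesets are scored independently
(no multivariate selection, so correlated probesets can all enter a
panel); the longitudinal features are simple per-subject slopes/means and
assume roughly linear short-range trajectories; and the clinician report
digitizes against fixed reference groups, so it is only as transportable
as those references. The stratified step-4 analysis multiplies tests —
nominal significance in a small stratum is weak evidence on its own,
which is exactly why the composite score weights it lowest.
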