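---
title: "Methods: cumulative pandemic adversity and mental health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative pandemic adversity and mental health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caindex)
```

## The problem this package addresses

During the first sixteen months of the COVID-19 pandemic, repeated online
questionnaires in three Dutch psychiatric case–control cohorts measured both
exposure to pandemic-related stressors (infection, bereavement, quarantine,
job loss, …) and mental health outcomes (depressive symptoms, anxiety
symptoms, loneliness). Average symptom trajectories in such cohorts were
nearly flat, which can hide substantial heterogeneity: people differed widely
in *how much* adversity they accumulated. `caindex` implements, as a tested
pipeline, the measurement and modelling machinery needed to ask whether
cumulative individual-level adversity predicts within-person changes in
mental health, and whether people with (chronic) pre-pandemic psychiatric
disorders are more vulnerable to it.

Because the underlying cohort data are access-restricted, the package pairs
the analysis machinery with a seeded synthetic cohort generator that emulates
the cohorts' structure and carries *known* injected effects, so every
modelling claim can be validated by parameter recovery rather than by
re-fitting inaccessible data.

## The Cumulative Adversity Index (CAI)

The observation window (1 April 2020 – 31 July 2021) is split into three
calendar subperiods tracking the national infection waves: April–August 2020,
September–November 2020, December 2020–July 2021 (closed intervals; the
boundaries are taken as fixed dates). The index is built from 15
questionnaire items grouped into nine exposure types:

1. **Weights.** Each item (or response level, for the course-of-infection
   item) carries a severity weight in points: e.g. own symptoms without a
   diagnosis = 1 point, an own diagnosis = 3, a hospitalised course = 5.
   The full table is shipped as data
   (`system.file("extdata", "cai_weight_table.csv", package = "caindex")`),
   so alternative weighting schemes drop in without code changes.
2. **Dependency groups.** Mutually dependent items (symptoms / diagnosis /
   course; the household equivalents; the three financial items) form groups
   of which only the highest endorsed weight counts within a wave.
3. **Wave maxima.** Within a subperiod, each exposure type keeps its highest
   score across the waves a participant completed.
4. **Subperiod totals and cumulation.** The nine type scores are summed per
   subperiod; the time-varying predictor at period *p* is the running sum of
   subperiod totals up to *p*. Under the canonical table the subperiod maxima
   are 15/16/16 (some items were fielded only in a subset of subperiods), so
   the theoretical cumulative maximum is **47** — `max_possible_score()`
   verifies this by enumeration. We treat the printed 0–47 range as the
   theoretical ceiling, not an observed sample range.
5. **Eligibility.** Participants contribute only if the index is computable
   in at least two subperiods. A missing subperiod contributes 0 to later
   cumulative sums and yields no outcome row for its own period; this
   follows the running-sum definition literally and avoids imputation.

The CAI enters the models unstandardised, in raw points, so coefficients
read as outcome change per CAI point.

## Instruments

* **QIDS** (16 items, 0–3) is scored into nine depression domains; sleep,
  appetite/weight and psychomotor items are domain maxima, the rest single
  items; total 0–27. The item-to-domain mapping follows the standard
  QIDS-SR16 layout and ships in the item dictionary.
* **BAI** (21 items, 0–3) is a plain sum, 0–63.
* **De Jong Gierveld loneliness** (6 items): "yes" and "more or less" score
  1 on negatively worded items, reversed on positively worded ones, total
  0–6. Whether a given cohort applied the reversal is data, not code: item
  polarity travels with the response, and marking all items negative
  recovers the unreversed variant.
* **Perceived mental health impact** (9 items, 1–5) is scored as the item
  mean; it anchors the alternative weighting (below).

Scorers never impute: any missing item yields a flagged missing score.
`cronbach_alpha()` provides the usual internal-consistency statistic for
item matrices.

## Pre-pandemic chronicity

Across the diagnostic waves attended between 2006 and 2016, chronicity is
the percentage of waves with any current (6-month) diagnosis of seven
disorders (MDD, dysthymia, GAD, panic disorder, social phobia, agoraphobia,
OCD). Groups: *none* (no lifetime diagnosis), *remitted* (lifetime diagnosis,
0% chronicity), *low–medium* (0–50%], *high* (50–100%]. Two deliberate
readings: the denominator is **attended** waves (missed waves do not count
against anyone), and the printed integer ranges "1–50%" / "51–100%" are
implemented as the half-open intervals (0, 50] and (50, 100] so that
non-integer percentages from missed waves remain classifiable. "Remitted"
requires any lifetime diagnosis with zero chronicity, which also covers
controls carrying only a lifetime diagnosis.

## The mixed models

For outcome \(y\) (period mean of observed wave scores, in instrument
units), participant \(i\), period \(p\):

\[
y_{ip} = \alpha + \tau_p + \beta\,\mathrm{CAI}_{ip} + \delta_{g(i)} +
\theta_{g(i)}\mathrm{CAI}_{ip} + \lambda\,\bar y^{\mathrm{pre}}_i +
\gamma^\top x_i + b_i + e_{ip},\qquad
b_i \sim N(0, \sigma_b^2),\; e_{ip} \sim N(0, \sigma_e^2)
\]

fitted by REML (`lme4::lmer`), so participants with incomplete periods
contribute their observed rows. Three tiers: *crude* (CAI + the outcome's
pre-pandemic mean), *adjusted* (adds chronicity group, age, gender,
education, partner status, period as a categorical 0/1/2 covariate, and
waves attended per period), *interaction* (adds CAI × chronicity group).
Design choices, made where the published description is open:

* **Random intercept only.** With at most three period-level observations
  per participant, random CAI or period slopes are weakly identified.
* **Wald inference.** 95% CIs as estimate ± 1.96 SE and normal p-values; no
  small-sample correction, since the intended cohort sizes (>1000) make it
  immaterial.
* **Per-outcome pre-pandemic adjustment** by default; a switch
  (`adjust_all_prepandemic`) adjusts for all three pre-pandemic means at
  once.
* **No multiplicity correction** anywhere; the 18 disorder-interaction tests
  carry an explicit caveat in the result metadata instead.

Descriptive group comparisons use Pearson chi-squared tests (no continuity
correction) and one-way ANOVA F-tests.

### Sensitivity analyses

*Per-disorder interactions.* Lifetime indicators for the seven disorders and
their CAI interactions replace the chronicity terms. The reference disorder
is chosen programmatically as the one whose interaction coefficient is
closest to zero in a preliminary all-disorders fit (an argmin rule — ties,
which have probability zero in continuous data, would resolve to the first
minimum).

*Impact-weighted alternative index.* One multiple regression of the
perceived-impact score on all nine cumulative exposure-type scores yields
standardized coefficients \(b_t\,\mathrm{sd}(x_t)/\mathrm{sd}(y)\), retained
with their signs. These are applied as per-type multipliers of the canonical
type scores, so the alternative cumulative index is
\(\sum_{\text{subperiods}}\sum_t w_t s_{tp}\). This keeps the index linear in
the weights; multiplying all weights by \(k\) scales fitted CAI slopes by
exactly \(1/k\), which the tests exploit as an identity check. A collinear
set of type scores (e.g. a duplicated column) is a hard error naming the
offending types.

## The synthetic cohort generator

`generate_cohort()` emulates: ~1377 participants; age truncated-normal
(mean 56.84, s.d. 13.01 on 28.5–86); about 62% female; four chronicity
strata; six biennial diagnostic waves 2006–2016 (the published design fixes
only the window, so biennial years are our choice); 15 pandemic waves spread
5/4/6 over the three subperiods at 2–8 week spacing; Bernoulli wave
nonresponse (0.8 per pandemic wave, 0.9 pre-pandemic). Per-wave exposure
items are independent Bernoulli draws whose odds are scaled by a per-stratum
multiplier (the adversity gradient) and a global scalar; the
course-of-infection item draws a severity level (0.7/0.2/0.1
mild/severe/hospitalised) when endorsed. Diagnostic indicators are drawn so
each participant's realized chronicity falls inside the assigned stratum's
defining range, which the tests verify by re-deriving the classification.

**Outcomes are generated on the period-mean scale** — the quantity the
models operate on — with a participant random intercept and period-level
residual; every wave in a period carries its period's outcome value, so the
"mean of observed waves" step reproduces it exactly and the injected
coefficients are recovered without attenuation. Instrument *items* are
additionally synthesized, approximately consistent with each wave's score,
purely to exercise the scorers. Outcomes are not clipped to the instrument
ranges by default (truncation biases slope recovery); `bounded_outcomes =
TRUE` clips to 0–27 / 0–63 / 0–6 for realism demonstrations.

Default injected effects: CAI slopes 0.54 / 0.82 / 0.22 points per CAI
point for depression / anxiety / loneliness; modest positive chronicity
offsets; zero CAI × chronicity interactions; pre-pandemic slope 0.5; small
period offsets; random-intercept and residual s.d. 2 per outcome.

### Calibration

`calibrate_exposure_multiplier()` tunes the single global odds scalar so
that the **period-1** mean CAI of named strata matches target values — the
period-1 convention is ours, as the published stratum means (6.37
high-chronicity, 5.27 no-lifetime) are not tied to a period. The expected
mean is computed analytically (per dependency group,
\(E[\max] = \sum_j (v_j - v_{j-1}) P(\max \ge v_j)\) with
\(P(\text{ever endorsed in }k\text{ waves}) = 1-(1-p')^k\), averaged over
binomial attendance conditional on at least one attended wave), so the
monotone bisection is free of Monte-Carlo noise. One scalar cannot hit
several stratum targets independently; the default per-stratum odds
multipliers (1 / 1.14 / 1.30 / 1.48) were therefore fixed once, at design
time, so that the analytic high-vs-none mean ratio matches the observed
6.37/5.27 near the calibrated regime (intermediate strata interpolate
geometrically), after which the scalar search minimises the maximum absolute
deviation across the named targets and errors if it exceeds the tolerance —
e.g. for any target above the attainable subperiod-1 maximum of 15.

### The parameter-recovery design

`recovery_config()` zeroes the chronicity offsets, interactions and period
offsets, so the **crude** tier is exactly the data-generating model and its
slope estimator is unbiased for the injected truth; all remaining structure
(exposure gradient, attendance, pre-pandemic adjustment) stays active. This
is the standard simulation design for validating an estimator: truth must
live inside the fitted model, otherwise omitted-variable bias is measured
instead of estimator bias. The confounded default configuration is retained
separately, and a dedicated test verifies that the crude tier *is* biased
there and that adding the adjustment set removes the bias.

Problem sizes used by the test-suite and the acceptance script — our choice
of a design dense enough for stable Monte-Carlo statements: 100 replicate
cohorts of n = 500 for slope recovery and CI coverage; n = 5000 for the
calibration check; 1000 random response sets for the brute-force index
oracle; 1000 null simulations for the type-I-error checks.

### What the generator does not emulate

Passing tests establish correctness of the pipeline's algebra and estimators
under the stated generative assumptions, not realism of any particular
dataset. Known simplifications: exposure items are independent across items
and waves (no trait persistence — "lives alone" can flip between waves — and
no co-occurrence structure, so synthetic CAI dispersion is smaller than the
observed s.d. of ~4); nonresponse is Bernoulli, not informative attrition;
instrument items are generated from a common severity rate, not an item
response model, so item-level psychometrics (e.g. observed alphas) are only
qualitatively realistic; diagnoses use one primary disorder plus at most one
comorbidity.

## Numerical choices and degenerate inputs

* Subperiod boundaries are closed calendar intervals; out-of-window dates
  are errors naming the window.
* Aggregation is max-based and therefore idempotent and order-invariant;
  both properties are tested.
* Zero observed waves in a subperiod is a missing-subperiod marker, never an
  exception; fewer than two computable subperiods marks the participant
  ineligible.
* Endorsing an item outside its availability mask, response levels outside
  the weight table, and inconsistent chronicity profiles (positive
  chronicity without a lifetime flag) are hard errors.
* With the random-intercept variance generated as zero, the REML estimate
  sits at the boundary in most realizations, where the mixed fit equals OLS
  to numerical precision; when sampling noise leaves a small positive
  variance estimate the fits differ at the order of that estimate. The
  OLS-equivalence test conditions on boundary fits for its strict (1e-4)
  comparison and bounds the others loosely.
* Noiseless generation leaves `lmer` at a degenerate optimum (singularity /
  convergence notes are expected and are captured on the result object);
  fixed effects are nonetheless exact, which the tests assert to 1e-6
  relative error.

## Limitations

The weight table is a reconstruction pinned by the published worked
examples, counts, availability footnotes and the cumulative maximum of 47;
other tables satisfying the same constraints would differ in unpinned cells,
which is why the table is data. The package validates methodology on
synthetic cohorts; applying it to real extracts (the external-data mode of
`run_pipeline()`) inherits all limitations of the underlying questionnaires
and of self-assigned severity weights.
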