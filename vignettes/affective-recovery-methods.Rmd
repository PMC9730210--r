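---
title: "Modelling positive affective stress reactivity and recovery in ESM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling positive affective stress reactivity and recovery in ESM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmrecovery)
```

## The question and the data

Experience sampling (ESM) protocols signal participants several times a
day and ask for momentary self-reports. `esmrecovery` analyses how
momentary *positive affect* (PA) behaves around minor daily stressors in
such data, comparing groups along a clinical-staging continuum
(patients with a mental disorder, individuals at risk, controls). Three
questions drive the design:

1. **Reactivity** — how much does PA drop at the prompt where the first
   stressor of a day is reported?
2. **Recovery** — how long does PA stay below its pre-stressor baseline
   afterwards, and how deep is the average deviation over that window?
3. **Staging contrasts** — do baseline PA, reactivity, and recovery
   differ between patients, at-risk individuals and controls?

The expected input is a long-format table with one row per *scheduled*
prompt: identifiers (`person_id`, `day_index`, `beep_index`), timing
(`scheduled_time`, `response_delay_min`), three PA items
(cheerful / relaxed / satisfied, 1–7), a bipolar event-pleasantness
rating (−3 … +3), and four current-activity items (1–7, with "I'm
skilled at this" reverse coded). Unanswered prompts are rows whose
response delay and items are missing. The reference design is 10
pseudo-random prompts per day in 90-minute blocks between 07:30 and
22:30 on 6 consecutive days.

## Measures

* **Positive affect**: mean of the three PA items; at least two observed
  items are required (a conventional EMA tolerance — the protocols this
  package targets do not state one), otherwise the score is missing.
* **Event-related stress**: the bipolar event rating is recoded to a 1–7
  unpleasantness scale (`4 − x`), and a prompt counts as event-stressed
  when the recoded value exceeds 4 — i.e. when the reported event was on
  the unpleasant side of the bipolar scale. The cut-off is exposed as
  `event_threshold`.
* **Activity-related stress**: mean of the four activity items after
  reverse coding; activity-stressed when above the scale midpoint 4
  (`activity_threshold`). The dichotomisation points are design choices:
  the negative half of the bipolar scale is the natural reading of "an
  unpleasant event was reported", and the midpoint split parallels it
  for the activity scale.
* **Composite stress**: presence of one or both types (logical OR).
  `pca_justification()` reproduces the usual sanity check for collapsing
  the five indicators into one presence measure (principal components on
  the correlation matrix, eigenvalue-above-1 retention by default).

## Compliance filtering

Only prompts answered within 15 minutes of the signal are treated as
measurement occasions, and answered prompts on which every PA and stress
item is missing are discarded with them; persons with fewer than 20
remaining prompts are then removed entirely. The two stages are logged
separately (unanswered / late / all-items-missing, then low-compliance
persons) so the accounting always reconciles: input = retained +
removed, at every stage.

## Outcome standardisation

The models use a standardised outcome `pa_z`. Two constructions are
implemented in `center_and_standardize()`:

* `"person_day"` — subtract each person's mean, then the person-day mean
  of the person-centred values, and divide by the overall (population)
  standard deviation of the result. This removes *all* person- and
  day-level location differences: within-person means of `pa_z` are
  exactly zero.
* `"grand"` — plain z-standardisation around the grand mean
  (the pipeline default).

The choice matters. Under `"person_day"` the between-group baseline
contrasts of the staging hypotheses are identically zero by
construction — a fully person-centred outcome cannot carry group-level
differences. Because those contrasts are a primary target of the
analysis (and are plainly nonzero in published staging studies on a
standardised PA outcome), the pipeline standardises around the grand
mean and lets the model's person and day random intercepts absorb the
level differences — which is what a three-level model does anyway. The
doubly-demeaned variant remains available for sensitivity analyses of
the purely within-person effects; within-day contrasts (reactivity,
recovery) are identical under both constructions up to the scale factor
between the two standard deviations.

## Trajectory coding

For each stress type, `code_time_since()` marks each included
person-day relative to the day's **first** stressor: the stressor prompt
is `t0`, the answered prompt immediately before it is the baseline
`t-1`, and the following answered prompts are `t1 … tK`. Days whose
first stressor falls on the day's first answered prompt have no baseline
and are excluded, as are stress-free days and persons who never report
the stress type; prompts before the baseline or beyond `tK` are excluded
with their own reasons. Restricting to the first stressor avoids
conflating the trajectory with cumulative later stressors; the
sensitivity models instead add an indicator for whether each follow-up
prompt is itself stressed.

Two open choices were resolved as follows:

* **Occasion indexing.** Labels are defined over *answered, valid*
  prompts, so a missed beep shifts `t1` to the next answered prompt.
  The alternative (indexing scheduled beeps and treating missed ones as
  gaps) is arguably closer to clock time but leaves holes in the
  contrast ladder; with ~90-minute gaps either reading is an
  approximation, and answered-prompt indexing keeps every modelled label
  observed.
* **Window length `K`.** Defaults are 1 follow-up prompt for
  event-related stress and 2 for activity-related and composite stress
  (configurable per type); prompts beyond `tK` are excluded rather than
  pooled so the baseline contrast stays interpretable.

## Models and inference

All models are three-level linear mixed models — prompts (level 1) in
days (level 2) in persons (level 3) — with random intercepts at the
person and day-within-person levels, fitted by maximum likelihood
(`lme4::lmer`, `REML = FALSE`), matching the convention of the
multilevel software this analysis family was developed in. Inference is
large-sample Wald: normal CIs for single coefficients and linear
combinations, chi-square for joint tests; no small-sample df
correction. Random slopes are available as a sensitivity option
(`random_slope_t0`) but off by default — nothing in the target design
identifies them well.

The hypothesis sequence mirrors the staging analysis:

* **Within groups (H1)**: a separate model per group with `time_since`
  as predictor, every `t0 … tK` compared with baseline `t-1`
  (`within_group_contrasts()`).
* **Group main effect and baseline contrasts (H2)**: group added as a
  predictor. The main effect is a joint Wald chi-square on the group
  dummies *of this model* — in the interaction model the dummies become
  baseline-specific quantities identified from far fewer effective
  observations, and the large-sample test is visibly anti-conservative
  there (the package's null-calibration test measures the size of the
  H2-model test).
* **Reactivity contrasts (H3)**: `time_since × group` interaction;
  the `t0` between-group contrast is the *difference in the change from
  baseline* (the interaction coefficient), i.e. a
  difference-in-differences, not the difference in expected level at
  `t0`.
* **Recovery (H4)**: the recovery window ends at the first follow-up
  prompt whose within-group deviation from baseline is no longer
  significant (per group); the overall window `t1 … tL` spans until the
  last group has recovered. Recovery is quantified as the *average
  deviation from baseline* across that window, and compared between
  groups through the corresponding average of interaction coefficients,
  with a delta-method Wald CI.

All models adjust for age (centred at the analytic-sample grand mean of
that model) and gender (female indicator); `covariates = FALSE`
reproduces the unadjusted variant.

**Multiplicity.** Every hypothesis is tested once per stress measure
(event, activity, composite), so each family holds three p-values.
`simes_correct()` applies the Simes–Hochberg step-up closure: sorted
ascending, the thresholds are α/3, α/2, α (printed as .02 / .03 / .05 at
two decimals for α = .05), and all hypotheses up to the largest rank
passing its threshold are rejected. The closure — rather than three
independent per-rank comparisons — is used because it is the standard
step-up procedure and because it makes decisions monotone in the
p-values; the two agree on the typical configurations.

**Non-convergence** is propagated, never repaired: contrasts from a
non-converged fit are reported as missing with an explanatory note.

## The synthetic-data generator

No raw staging-study data are distributable, so `generate_esm()`
produces datasets with the statistical structure the analysis assumes,
with the planted truth exported (`ground_truth()`), and the whole
pipeline is validated by parameter recovery. The latent outcome for
person *i*, day *d*, prompt *t* is

y_idt = β₀g + u_i + v_id + r_g·[t = t0] + d_gk·[t = k-th post-stressor
prompt, k < L_g] + β_age·age_i + β_gender·female_i + ε_idt,

with u, v, ε independent normals. The `"paper-like"` preset plants the
effect sizes typical of published staging contrasts: baseline offsets
0 / −0.28 / −0.44 (controls / at-risk / patients), reactivity −0.32 /
−0.38 / −0.38, and recovery lags 1 / 2 / 2 prompts, with post-stressor
deficits decaying geometrically (factor 0.3 per lag, so the
still-depressed `t1` deficit is ≈ −0.11 for patients and at-risk).
Stress indicators are correlated Bernoulli draws (event ~0.15, activity
~0.175 per prompt, co-occurrence odds ratio 2); 8% of persons never
report stress, exercising that exclusion path. Compliance is a
per-person Beta-heterogeneous answer probability (group means 0.82 /
0.78 / 0.75) with uniform response delays extending slightly past the
15-minute rule so the delay filter has work to do.

Three calibration details matter for interpretation:

* **Scale.** The analysis z-standardises the outcome, so planted
  effects are meaningful only relative to the total outcome SD. The
  default variance components (person 0.25, day 0.05, residual 0.65)
  plus the fixed-effect variance put the total at ≈ 1, and
  `ground_truth()` converts every planted effect to the analysis scale
  by dividing by the analytically expected SD (integrating the stress
  process over the Binomial number of valid prompts per day and the
  geometric first-stressor position).
* **Occasion indexing.** Trajectory effects are indexed over prompts
  answered within the protocol's 15-minute validity window — the
  occasions the analysis sees after filtering. Indexing over all
  answered prompts instead would misalign the generator's labels with
  the analysis's whenever a late-answered prompt is dropped, and
  attenuate recovered reactivity noticeably.
* **Items.** By default the PA items are noisy discretised 1–7 versions
  of the latent outcome; discretisation (noise, rounding, clipping)
  shrinks every planted effect by several percent on the standardised
  scale, which is realistic but makes exact parameter recovery
  ill-posed. The `"paper-like"` preset therefore emits the latent
  outcome directly in the PA items (`emit_latent = TRUE`) so that the
  planted values are exactly the estimands; the discretised path is
  exercised by the default configuration and the `"high-missingness"`
  preset.

What the generator does **not** emulate: stress clustering in time or by
person beyond the never-stressed mixture, affect–stress feedback
(stress indicators are exogenous), graded stressor intensity, item-level
response styles, or diurnal affect cycles. Passing parameter-recovery
tests therefore shows the estimator chain is correct for the assumed
data-generating process, not that real diary data satisfy it.

## Numerical choices and degenerate inputs

* Compliance percentages round half-up to integer percent.
* Standardisation uses the population SD; a zero-variance outcome yields
  zeros with a warning, and persons with a single observed prompt are
  excluded from person-centering with a warning.
* A missing stress score yields a `FALSE` presence flag plus an explicit
  missingness marker, keeping "no stress" distinct from "not assessed".
* `lmer` fits run with derivative checks off for speed; convergence is
  tracked from the optimiser return code and warnings, and boundary
  (singular) variance estimates are accepted as converged.
* Wald CIs use the normal 0.975 quantile; p-values are two-sided.
* The group main-effect test refuses aliased group terms (singular
  sub-covariance) by naming them rather than dropping them.

## Problem sizes in the shipped checks

The package's own validation uses sizes chosen to make Monte-Carlo
checks sharp but cheap: trajectory-coding oracles on ≈ 216 person-days;
likelihood oracles on ≤ 200-row fits; parameter recovery with 200
replicates of 100 persons per group; test-size calibration with 500
replicates of 60 persons; and the qualitative recovery-ordering check
with 60 replicates of 150 persons per group. At those sizes the
recovery-ordering check is demanding by construction: a planted `t1`
deficit of −0.11 SD against a within-group standard error near 0.05
gives each patient-type group only ~60% power at `t1`, so the full
ordering (both clinical groups still depressed at `t1`, everyone
recovered at `t2`, controls already recovered at `t1`) reproduces in a
minority of replicates — a sample-size statement, not an estimator
defect; the same check passes easily when the planted deficits are
enlarged relative to noise.

## Limitations

Reactivity at `t0` is cross-sectional (stress and affect are reported at
the same prompt), so its direction is not identified; the recovery
window, defined over strictly later prompts, is the better-identified
quantity. The dichotomous stress operationalisation discards intensity.
Event-related stress refers to the most important event since the last
prompt, so its `t0` is blurred by up to one sampling interval. All
inference is large-sample; with very few persons per group the joint
group tests become anti-conservative if computed from the interaction
model (use the H2 model, as the pipeline does).
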