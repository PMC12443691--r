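---
title: "Clone-censor-weight emulation of RRT initiation timing trials: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-censor-weight emulation of RRT initiation timing trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrtccw)
```

## The question and why naive analyses fail

In critically ill patients with acute kidney injury (AKI), clinicians must
decide *when* to start renal replacement therapy (RRT). Observational data
on this question are doubly treacherous. First, initiation is confounded:
sicker patients (higher SOFA, vasopressors, sepsis) start RRT earlier and
also die more. Second, a comparison of "ever treated" versus "never
treated" subjects misclassifies the person-time a starter had to survive
*before* initiation as treated person-time — immortal time bias — which by
itself manufactures a survival advantage for treatment.

`rrtccw` implements the target-trial-emulation answer: define eligibility
and time zero as a hypothetical randomized trial would, duplicate ("clone")
every eligible subject into each treatment strategy at time zero, censor a
clone at the hour its subject's data deviate from the assigned strategy,
and remove the selection bias created by that artificial censoring with
time-varying stabilized inverse-probability weights. Two emulated trials
are supported: a broad trial enrolling at KDIGO stage >= 1 and a severe
trial enrolling at stage 3.

## Eligibility and time zero

Subjects are screened on the hourly grid. Hour-level criteria: KDIGO
creatinine stage at or above the trial threshold (staged against the first
recorded creatinine; stage 1 at >= 1.5x baseline or a >= 0.3 mg/dL rise
within a rolling 48 h window, stage 2 at >= 2.0x, stage 3 at >= 3.0x or an
absolute value >= 4.0 mg/dL; urine-output criteria are out of scope),
respiratory rate above 10 breaths/min *at the candidate hour* (one of
several defensible operationalizations; it is the one implemented),
alive, RRT-naive, and at least 12 h of hospitalization accrued. Subject
level criteria: ICU stay exceeding 72 h, no chronic kidney disease, full
code status. Time zero is the *first* hour within the 72 h eligibility
window at which all criteria hold. Exclusions are tallied sequentially per
criterion, CONSORT style.

Two consequences are worth flagging. The ICU-stay criterion conditions on
surviving (or at least remaining in the ICU) 72 hours, which shapes the
eligible population; it is applied because the emulated protocol applies
it. And eligibility is evaluated on the hourly grid only — no interpolation
between hours.

## Missing data

Time-varying panel variables are imputed by last observation carried
forward ("the value from the preceding hour"); a leading gap has no
preceding hour and is seeded from the subject's first observed value.
Baseline variables are imputed by chained equations with predictive mean
matching (donor pool k = 5, 10 sweeps); records missing the sex indicator
are dropped outright. The analysis uses a single completed table; `m > 1`
tables are available for sensitivity diagnostics, and pooling across
imputations (Rubin's rules) is deliberately not performed because the
emulated protocol does not describe it.

## The clone-censor-weight design

Each eligible subject is cloned into an **early** arm ("initiate RRT
within the 72 h grace period") and a **never** arm ("do not initiate").
Deviations are assessed at hourly checkpoints: the never clone is censored
at the hour RRT factually begins (at any hour), the early clone at the end
of the grace period if RRT has not begun by then (initiation strictly
before hour 72 counts as within the grace period). Deaths at a would-be
censoring hour take precedence over censoring, so deaths during the grace
period are retained in *both* clones. Administrative censoring occurs at
the 30/90-day horizon; hospital discharge does not end mortality
follow-up. Person-time is expanded hourly through the grace period (where
the weights change) and daily thereafter.

## Stabilized weights

Let `p(t | X_t)` be the fitted probability of initiating RRT at hour `t`
since eligibility given current covariates (the **denominator** model:
pooled logistic over person-hours at risk of initiation, with a natural
cubic spline in `t`, baseline covariates age, sex, CCI, sepsis, vasoactive
drug use, time from ICU admission to eligibility, and current SOFA, heart
rate, respiratory rate, diastolic pressure, SpO2), and `p0(t)` its
**numerator** analogue from a marginal model (intercept + time spline
only). The models are fitted on person-hours over the whole window in
which initiation can be observed, not only the grace period: the
never-initiate clone deviates at *any* factual initiation hour, so its
censoring weights must keep cumulating after the grace window closes.
The weight of a clone at hour `t` is the cumulative product over
checkpoints `s <= t` of the adherence-probability ratio: `(1 - p0)/(1 - p)`
for an hour still untreated, and `p0/p` at the early clone's initiation
hour. Early-arm weights freeze at initiation (the strategy is resolved);
person-time weights are truncated at the 1st/99th percentiles by default
(untruncated diagnostics are always reported).

Two design choices deserve explanation.

**Marginal numerator.** A numerator conditioning on baseline covariates
would leave baseline confounding to the outcome model and the weighted
arms would *not* balance baseline covariates. Because the design goal —
and the diagnostic standard (all absolute standardized mean differences
below 0.1 after weighting) — is covariate balance between the weighted
arms, the default numerator is marginal. Baseline covariates can be moved
into the numerator via `weight_model_spec()` if only time-varying
confounding is to be weighted.

**Uniform cumulative rule.** Every untreated hour contributes
`(1 - p0)/(1 - p)` in both arms; the early clone's initiation hour
contributes `p0/p`. The products are then the full likelihood ratio of the
observed timing under the marginal versus the individual initiation
hazard. The tempting shortcut of weighting an initiator by the single
ratio at the initiation hour leaves the cumulative selection of the
untreated risk sets uncorrected; in the package's own synthetic null
experiments it leaves several percentage points of residual confounding.

## What the early arm estimates: the grace-period regime

"Initiate within 72 h" is not a point intervention; the analysis targets
the *natural-timing* regime: initiation proceeds at the naturally observed
pace, conditioned to fall inside the grace window. The comparator is the
emulated trial's delayed-or-never arm: no initiation during the grace
window, with the natural initiation process free to resume afterwards.
The hazard-based analyses (weighted Cox, weighted product-limit curves)
target this contrast directly through the weighted risk sets.

For *fixed-horizon risks* one more calibration is needed. Subjects dying
during the grace period before initiating are adherent to both strategies
and enter with their cumulative weight; but relative to the regime, those
always-adherent deaths carry several times their share of the normalized
weight mass (the initiator mass integrates the within-grace initiation
probability `F0 ~= 0.2`, the death mass does not). `resolved_clone_weights()`
therefore also reports regime-calibrated weights: initiator weights divided
by `F0` (the marginal within-grace initiation probability under the
numerator model) and grace-death weights scaled by the remaining timing
mass `(F0 - F0(tau))/(1 - F0(tau))/F0`. Without this calibration the
early-arm risk is biased upward by 2-4 percentage points *even under a
null effect*; with it, the synthetic null experiments are centred on
zero. The standardized-mean-difference balance table compares the
weighted arms with the same calibrated weights, since the uncalibrated
composite inherits the grace-death over-representation as residual
severity imbalance.

## Outcome models

* **IPW Cox**: arm effect on the hazard, adjusted for the time-zero
  physiology covariates (SBP, MAP, temperature, pH, bicarbonate, lactate,
  hemoglobin, BUN, creatinine), Efron ties (an hourly grid guarantees
  ties), robust sandwich errors clustered on the *subject* — clones are
  copies of one person. Consecutive person-time rows with equal weights
  are merged before fitting; the partial likelihood is invariant to that
  split. Proportional hazards are checked with scaled Schoenfeld
  residuals against Kaplan-Meier-transformed time.
* **Weibull AFT**: the sensitivity model that does not assume proportional
  hazards; one record per clone with its resolved weight, robust clustered
  errors. The exponentiated arm coefficient is the acceleration factor
  (AF); AF < 1 is reported as a percent reduction in survival time, AF > 1
  as a multiplicative lengthening. On Weibull proportional-hazards data
  with shape `k` the two parameterizations satisfy `HR = AF^(-k)`, which
  the test suite uses as a self-consistency check.
* **AIPW**: doubly robust fixed-horizon risks
  `psi_a = mean(m_a(X)) + sum(D_a * sw * (Y - m_a(X))) / sum(D_a * sw)`,
  with `D_a` adherence through the grace period, `sw` the regime-calibrated
  resolved weight, and `m_a` a weighted logistic outcome model fitted among
  adherent clones. The augmentation term is Hajek-normalized: with a grace
  period the expected weight mass is the adherence probability, not 1, and
  the unnormalized estimator is not doubly robust. Confidence intervals
  come from influence functions (covariance-aware for the risk
  difference, since both risks are estimated on the same subjects).

## The synthetic cohort generator

The generator (`simulate_cohort()`) emulates the structure of an hourly
ICU EHR extract and supplies what real data never can: counterfactual
ground truth. Its defaults are calibrated to the magnitudes seen in ICU
AKI cohorts: mean age 65 (SD 15), 40% female, CCI ~7, 62% sepsis, hourly
vitals/labs as mean-reverting AR(1) processes around typical ICU values,
SOFA as a random walk with Normal(0, 0.25) hourly steps clipped to 0-24
(organ-failure scores evolve on a time scale of days; per-hour unit-SD
jumps would be clinically implausible and would give the time-varying
initiation hazard so much hour-to-hour swing that the
inverse-probability weights develop unusable tails), creatinine as a
geometric random walk with subject-specific upward drift (so a subset
progresses through the KDIGO stages), ~50% of subjects eligible for the
broad trial, ~21% of eligible subjects initiating RRT within 72 h of
eligibility, ~20% ninety-day mortality among the eligible with deaths
front-loaded into the acute phase (30-day deaths ~75% of 90-day deaths),
and initiation gated on a manifest AKI episode and driven by current
SOFA, sepsis, vasopressors and age — sicker patients start earlier, and
every initiation driver is a covariate of the default weight model.
Death is simulated hourly while the covariate panel runs (7 days) and
daily thereafter to day 90, from a logistic hazard in current severity
with a declining time trend.

`simulate_counterfactual_truth()` replays the death process under both
strategies with the same uniform draws (shared randomness): a null effect
gives a risk difference of exactly zero, a protective effect can only
lower the early-arm risk, and factual outcomes coincide with the followed
strategy's potential outcome. The early strategy's initiation hour is
drawn from the cohort's marginal within-grace timing distribution by
default (`timing = "natural"`, the regime the weighted analysis targets);
`"immediate"` (initiate at time zero) and `"own"` (the subject's own
natural hour, forced at the grace end) are also available. A
stage-dependent effect (`scenario = "stage_split"`) makes the clinically
interesting dichotomy constructible: harm in stages 1-2, benefit in
stage 3, so the broad trial shows net harm while the severe trial shows
benefit.

What the generator does *not* emulate: urine output (and hence
urine-output KDIGO criteria), ICU readmissions, treatment effects on the
covariate process (RRT lowers creatinine in reality; here it acts on the
death hazard only), informative missingness (holes are injected completely
at random), and calibration to any particular database's joint
distributions. Passing tests therefore demonstrate that the estimators
recover known truths under realistic-looking confounded longitudinal
structure — not that any particular clinical estimate is correct.

## Numerical choices and degenerate inputs

* Natural cubic spline with 3 internal knots (df 4) for time since
  eligibility; reduced automatically when the risk set has too few
  distinct hours.
* Treatment-hazard models are fitted by direct `glm.fit` on a hand-built
  model matrix (the risk set has one row per person-hour); suspected
  separation is reported with the offending covariate (SD-standardized
  coefficient beyond 10).
* Fitted adherence probabilities of exactly 0 or 1 abort with advice to
  truncate or respecify.
* Clones censored at time zero (e.g. the never clone of a subject
  initiating at its eligibility hour) carry no person-time and are
  dropped; zero-time clones are likewise dropped from the AFT fit.
* Ties: death at a censoring hour counts as an event; initiation and
  death in the same hour resolve as initiation-then-death.
* Constant covariates are dropped from model matrices; perfectly
  collinear covariates yield infinite VIFs with a warning.
* 30-day estimates are computed by administratively censoring the same
  machinery at day 30, so the two horizons are mechanically consistent.

## Validation problem sizes

The test suite validates the pipeline end to end with: 150 null cohorts
(n = 1000) for interval calibration of the weighted Cox and the AIPW risk
difference; 80 protective cohorts (n = 2500) against the counterfactual
truth (the generator's effect-recovery experiments are stable from about
n = 2000 upward, and these sizes keep the default suite comfortably
interactive); 100 null cohorts (n = 1200) for the immortal-time-bias
comparison with the naive ever-vs-never Cox; 25 cohorts (n = 4000) per
nuisance-misspecification configuration for the double-robustness check;
and single larger cohorts (n = 5000-6000) for AFT recovery and weight
diagnostics.

## Known limitations

* The AIPW adherence indicator is resolved at the grace boundary; factual
  initiations after the grace period are part of the comparator strategy
  (delayed-or-never), not censored from it.
* Influence-function intervals are first-order. The implementation
  propagates the nuisance-model estimation into the influence function
  (numeric chain terms through the weight machinery, analytic for the
  outcome model), but in small cohorts (around a hundred initiators) the
  realized sampling spread of the weighted estimators still exceeds the
  first-order prediction by a quarter or so, and the AIPW intervals
  under-cover accordingly. Subject-level bootstrap
  (`aipw_bootstrap()`) is the alternative when interval fidelity matters
  more than runtime.
* Cross-fitting of the treatment-hazard models is available
  (`fit_treatment_hazard_crossfit()`) but off by default: with few
  initiation events per fold it increases weight noise rather than
  reducing bias.
* The weight models are parametric logistic; no machine-learning
  propensity models are provided.
* Competing risks are not modelled (all-cause mortality only), and the
  Cox diagnostic is the only time-varying-coefficient machinery included.
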