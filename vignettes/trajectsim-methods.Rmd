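---
title: "Modelling disease trajectories with trajectsim: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disease trajectories with trajectsim: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`trajectsim` implements a discrete-time state-transition microsimulation of
chronic-disease trajectories, with prostate cancer as the worked disease
model. A man enters the model at diagnosis in one of six primary management
strategies -- active surveillance (AS), watchful waiting (WW), radical
prostatectomy (RP), radiotherapy (RT), antiandrogen monotherapy (AA) or
GnRH agonists (GNRH) -- together with a treatment-specific ordinal risk
category (3 levels for AS, 6 for WW and RP, 8 for RT and the two
androgen-deprivation states). Follow-up is discretised into 4-week steps.
At the end of each step he either remains in his state or moves along a
directed edge of the transition graph; transitions are irreversible, and
the process ends in one of two absorbing states, death from prostate
cancer or death from other causes, or at the horizon (326 steps, i.e.
`floor(25 * 365.25 / 28)` -- 25 years).

Transition probabilities depend on attained age, the time-updated Charlson
comorbidity index (CCI, 0/1/2/3+), treatment history, and the risk
category. Each simulated step resolves three draws, in a fixed order:

1. **Vital status.** A Bernoulli draw for prostate-cancer death from one
   logistic model, then -- conditional on surviving it -- a draw for
   other-cause death from a second logistic model. The per-step
   probability of death from any cause is therefore
   `p1 + (1 - p1) p2`, and a cancer death suppresses every later draw of
   the step.
2. **Treatment change.** For survivors, a single multinomial-logistic
   draw over the origin state's treatment destinations, with "stay" as
   the reference outcome. One multinomial model per origin (rather than
   separate per-edge logistic models) guarantees that the within-step
   destination probabilities sum to at most one without renormalisation.
   The change from AS to WW is the one exception: it is produced by a
   deterministic age/CCI threshold rule (below), checked before the
   stochastic draw. On a change, the new state's risk category is either
   inherited unchanged (RP to adjuvant/salvage radiotherapy, whose
   category space coincides with RP's) or drawn from a proportional-odds
   model for entry into the destination.
3. **Comorbidity.** For survivors, a logistic draw for "any CCI increase
   this step", followed by a zero-truncated Poisson draw for the
   increment size, capped so that CCI never exceeds 3. The CCI model is
   state-specific. The update takes effect from the next step, so all
   draws within a step see the step-start comorbidity level.

Estimation inverts the same structure on person-period ("long") data: one
row per man per 4-week step alive, with age updated as
`age_at_diagnosis + 28 t / 365.25` (age at the end of step `t`), CCI
updated the row after each increase, and the row's outcome one of stay,
change (with destination), or either death. Because estimation and
simulation share one covariate vocabulary (`default_covariate_specs()`)
and one draw order, a model fitted on expanded data is immediately
simulable -- and a cohort generated by the simulator and re-expanded
reproduces the generated outcomes row for row, which the test suite
exploits heavily.

## Parameters that matter

* `step_days = 28`: the discretisation unit. All probabilities are
  per-4-week-step probabilities, not rates.
* `horizon_steps = 326`: 25 years of follow-up. Landmark summaries use
  step `ceiling(y * 365.25 / 28)` for year `y` (131, 196, 261 for 10, 15,
  20 years).
* AS-to-WW thresholds, `default_as_ww_thresholds()` = 80/75/70/65 years
  for CCI 0/1/2/3+: a man on AS switches to WW (management without
  curative intent) in the first step at the end of which his attained age
  reaches the threshold for his current comorbidity level. The switch is
  not a dated registry event, so it is modelled as a deterministic rule
  rather than fitted; the rule is configurable and is applied identically
  by the generator and the simulator. The boundary is inclusive
  (`age >= threshold`).
* Covariate encodings: age enters linearly, centred at 70 and scaled per
  decade (`(age - 70) / 10`); CCI as three level indicators in the death
  models and as a 0..3 score elsewhere; the current state as indicators in
  the death models (which pool all states); treatment history as a
  previous-RP indicator; risk category as an ordinal 0-based score. A
  per-level indicator basis for risk category was considered and rejected
  as the default: category spaces differ between states (3 to 8 levels)
  and a shared indicator basis is weakly identified in strata where high
  categories are rare. Any encoding in the term vocabulary (including
  per-level `risk<k>` indicators and a time-in-state term, excluded from
  the defaults) can be requested per model via the `specs` argument.
* Estimation tolerances: logistic fits converge to a relative
  log-likelihood change below 1e-8 with at most 100 iterations;
  quasi-separation (any |coefficient| above 15) or non-convergence
  triggers a ridge refit with penalty 1e-6 and a warning. Multinomial
  fits use a relative tolerance of 1e-12 and up to 500 iterations.
* Zero-truncated Poisson increments: fitted by maximum likelihood, with
  increments that hit the CCI cap treated as right-censored (an observed
  capped increment only says the true increment was at least that
  large). A state with rows but no observed increases gets a floored
  intercept (per-step probability 1e-6) with a warning.
* Multiple imputation: 5 imputation data sets by default, 10
  chained-equation cycles, posterior-draw (never best-prediction)
  imputation. Coefficients are pooled as across-imputation means and
  variances by the usual combination rule `W + (1 + 1/m) B`. The
  simulator consumes pooled point estimates.

## The synthetic registry

Real nationwide registry data of this kind are not redistributable, so the
package ships a generator whose ground truth is fully known. It emulates:

* the published cohort composition of 118,743 men across the six primary
  strategies (23,649 / 7,286 / 32,537 / 19,019 / 7,178 / 29,074 for the
  AS pathway, WW, RP, RT, AA, GnRH), per-strategy age distributions with
  the published medians and interquartile ranges (truncated normal,
  40-95 years), per-strategy baseline CCI distributions (marginal CCI 0
  about 66.5%), and per-strategy entry risk-category distributions;
* registry mechanics: diagnosis dates uniform over 1992-2014, dated
  treatment-change and comorbidity events (an event in step `t` is dated
  `diagnosis + 28 t` days, so expansion is exactly invertible), horizon
  censoring, optional administrative end-of-follow-up, left truncation
  semantics, and staging-like "determinant" vectors at each state entry
  that are reported at diagnosis but maskable at deferred entries
  (missing completely at random by default, with the realised category
  hidden along with them).

The transition parameters themselves are not published, so they are free
parameters of the configuration. The defaults were chosen once by
back-calculating constant-hazard approximations from cumulative
incidences typical of such a cohort and from a handful of published
landmark anchors (roughly a fifth of RP men reaching adjuvant/salvage
radiotherapy within ten years; a few percent of curatively treated men on
GnRH agonists by 10-20 years), with nonzero age, comorbidity, risk and
history effects throughout. Under the defaults a 20,000-person cohort
shows, for example, RP-to-RTADJ cumulative incidence near 0.22 at ten
years and RT-to-GnRH near 0.05.

What the generator deliberately does **not** emulate: clinical semantics
of stage, grade or PSA (the determinants are abstract correlated
Gaussians whose only role is to give the imputation model something to
chain on); calendar-period effects on treatment choice; dependence of
censoring on covariates; informative (non-MCAR) missingness, although a
rate hook exists. Passing round-trip tests on synthetic data therefore
demonstrates the *self-consistency* of the estimation-simulation
pipeline -- that the pipeline recovers the mechanism that generated the
data at realistic scales -- not the clinical adequacy of any particular
fitted model on real registry data.

## Numerical and design choices

* **Step intervals** are half-open, left-exclusive: step `t` covers days
  `(28(t-1), 28t]` after diagnosis; an event dated inside becomes the
  row's outcome. A death and a treatment change in the same step resolve
  to the death, matching the simulation's draw order (vital status
  first, so a change can never co-occur with a death in one step).
* **Left truncation** (delayed entry at a calendar date): persons whose
  follow-up ended before the date are dropped; the rest contribute rows
  from the first step starting on or after the date, entering in the
  state, category, CCI and history they occupy there -- reconstructed
  from their earlier events, which produce no outcome rows. How a man's
  state at the truncation date is reconstructed is this package's
  explicit choice; calendar time itself is never a covariate, truncation
  only reshapes the risk sets.
* **Second-transition curves** keep the time-since-diagnosis clock, with
  delayed entry at the first-transition step, so landmark years read on
  the same axis as first-transition curves. The alternative clock (time
  since first transition) is computable from the same summaries but is
  not the default.
* **Comorbidity attribution**: the CCI draw of a step uses the state
  occupied *during* the step (the person-period row's state), not the
  destination of a same-step change, keeping the estimator and the
  simulator congruent on rows where both a change and a CCI increase
  occur.
* **Reproducibility**: all simulation randomness comes from a
  counter-based generator keyed on (seed, person, replicate, step, draw
  slot) -- splitmix64 hashing, exposed as `counter_uniform()`. Results
  are therefore invariant to cohort ordering and batching, replicate
  streams are independent by construction (the registry generator draws
  from replicate stream 0, simulation from streams 1..R), and the pure-R
  single-step reference (`step_person()`) consumes bit-identical
  uniforms to the compiled engine, which the tests verify
  trajectory-by-trajectory. Simulator streams are deliberately *not*
  coupled to generator streams: common random numbers would make
  observed and simulated curves agree almost by construction and
  validate nothing beyond parameter recovery.
* **Degenerate inputs**: zero-probability mechanisms simulate to the
  horizon; a destination with no observed events is dropped from its
  multinomial with a warning (probability zero at simulation time); an
  ordinal entry model with fewer than two observed categories is a
  structured error (or, inside the full-pipeline fit, an
  empirical-distribution fallback with a warning); an intercept-only
  proportional-odds fit uses the closed-form cumulative-logit MLE.
* **Problem sizes** used by the packaged checks: the analytic-oracle and
  round-trip checks run at 10,000 synthetic persons (split 50/50, 100
  simulation replicates), parameter recovery at 20,000, the imputation
  checks at 4,000-5,000 with 20% masking. These sizes make strata large
  enough for stable estimation while keeping the full suite quick on one
  core.

## Known limitations

* **Sampling noise floors in internal validation.** An observed
  cumulative-incidence curve estimated from a stratum of a few hundred
  men has a sup-norm noise floor of several percentage points; at
  5,000-person validation halves the smallest strata (AA, WW entrants)
  sit near 300 men, so observed-versus-simulated sup-norm differences of
  0.03-0.06 arise from sampling alone even when simulating from the true
  mechanism, and second-transition strata are smaller still. Agreement
  much below those floors should not be expected -- or trusted -- at
  that scale; at the full published cohort size (118,743) the same
  floors drop to about a percentage point.
* The risk-category process is frozen within a state: categories change
  only at treatment changes, and no within-state progression is
  modelled.
* No frailty or random effects; no time-varying baseline hazard within a
  state beyond what age and CCI carry; variance estimation stops at the
  imputation-combination rule (no bootstrap confidence bands).
* Missingness handling assumes the masked deferred categories are
  missing at random given the imputation predictors; an origin category
  that is itself hidden is backfilled with the observed median rather
  than chained.
* No external validation: all validation machinery compares a cohort
  with simulations of that same cohort.
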