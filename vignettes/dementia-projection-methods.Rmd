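---
title: "Methods: dementia incidence trends and multi-state prevalence projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dementia incidence trends and multi-state prevalence projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Forecasting how many people will live with dementia requires more than
extrapolating prevalence: age-specific incidence is falling while life
expectancy rises, so the pool of people old enough to be at risk grows
even as their per-year risk shrinks. `demproj` implements a complete
pipeline for this problem on biennial ageing-panel data: an operational
dementia case definition, three estimators of the calendar trend in
incidence (of increasing robustness to selective attrition and competing
mortality), calibration of an eight-state discrete-time Markov model, an
annual cohort projection engine with entering cohorts, and Monte Carlo
uncertainty propagation. Because real panel microdata of this kind are
access-restricted, the package ships a synthetic cohort generator with
known ground truth; it defines the study conditions under which every
estimator and the whole pipeline are validated.

# The case definition

Cognitive state is measured by a battery of tests (orientation to time;
immediate and delayed word recall; verbal fluency; numeracy at waves 1, 4
and 6; literacy at wave 6), grouped into three domains: concentration,
memory, and executive function. Each test is z-scored against the pooled
ages-50-80 reference population *within education stratum* (three
levels), and each domain composite is rescaled to unit reference SD so
the impairment threshold means the same thing in every domain.

* **Domain impairment**: z at or below -1.5 (boundary inclusive -- "1.5
  SD below the mean or lower").
* **Cognitive impairment (CIND)**: impairment in two or more of the
  observed domains; assessments with fewer than three answered tests are
  invalid. Impairment is rescinded as transient when the average
  standardised score improves by at least 1 SD at the consecutive wave.
* **Functional impairment**: difficulty with one or more of seven
  activities of daily living; impairment reported at exactly one wave
  with full recovery at all later observed waves is transient.
* **Dementia**: cognitive *and* functional impairment at the same wave,
  or an informant-questionnaire (IQCODE) score of 3.6 or more (the
  conservative end of the conventional 3.3-3.6 range, inclusive) with
  functional impairment, or a reported doctor diagnosis. Onset is dated
  at the mid-point between the ascertainment wave and the latest previous
  assessment; when caseness hinges solely on numeracy, between the two
  consecutive numeracy-bearing waves. Transience at the last analysis
  wave is resolved with the following wave where available; that wave
  contributes nothing else (neither caseness nor the standardisation
  reference), so appending it never changes earlier-wave decisions.

Two properties of this definition matter for testing. First, it is
deliberately *specific* rather than sensitive (moderate-to-severe cases).
Second, the transience rule is not monotone wave-by-wave: artificially
lowering a single wave's scores can manufacture a `>=1` SD "improvement"
at the next wave and rescind an impairment. The monotonicity that does
hold -- and that the property tests assert -- is under a uniform
downward shift of a person's scores or additional ADL impairments.
Partially missing domains count toward "two or more" among the observed
domains only, and such assessments carry a `partial_domains` flag.

# Trend estimators

Events are interval-censored at two-year waves, so all three estimators
are discrete-time per-epoch formulations rather than continuous-time
hazard models; this is the exact likelihood for panel-ascertained onsets.
All include terms for age, age squared, sex, age-by-sex and calendar
year; the per-year incidence odds ratio (OR) is the exponentiated
calendar coefficient, and `100 * (1 - OR)` is the relative annual
decline in percent.

1. **Naive** (`fit_naive_trend`): logistic per-epoch hazard among
   participants under observation; post-dropout epochs are excluded and
   the epoch in which a dementia-free participant dies counts as an
   at-risk, no-event epoch (the discrete analogue of censoring at death).
   Onsets masked by death within an epoch are lost, and attrition that
   selects on cognitive decline progressively cleans the risk set, so
   this estimator is biased when either mechanism operates.
2. **Competing risks** (`fit_competing_risks_trend`): a multinomial
   no-event / dementia / death model on the same epochs. Because death is
   its own outcome category, the dementia-versus-no-event logit estimates
   the onset hazard conditional on surviving the epoch, which removes the
   death-masking dilution; with declining mortality the estimate is
   systematically steeper than the naive one. With no deaths in the data
   the two estimators coincide.
3. **Joint model** (`fit_joint_model`): a shared-random-effects model of
   the longitudinal average standardised score and the event process.
   The longitudinal submodel is a linear mixed model (ML, via `lme4`)
   with fixed effects for age at entry and its square, time since entry
   and its square, sex, calendar year, education and midlife
   obesity/hypertension/diabetes, and correlated random intercepts and
   *age* slopes. The event submodel is a per-epoch logistic hazard whose
   linear predictor adds `alpha_value * m_i(t)` and
   `alpha_slope * m_i'(t)`, the subject-specific latent score and slope.
   Its parameters maximise the joint marginal likelihood with the random
   effects integrated out by adaptive Gauss-Hermite quadrature (9 points
   per dimension by default, 81 nodes, centred and scaled per person on
   the empirical-Bayes posterior; a single-node Laplace-style fallback
   guards non-convergence), holding the longitudinal parameters at their
   ML estimates -- the exact conditional decomposition of the joint
   likelihood, so the event-side estimates remain consistent while
   keeping the fit tractable at n ~ 18,000. Dropout that depends on the
   latent level or slope is ignorable *given the random effects*, which
   is precisely the attrition mechanism being corrected.

From the fitted joint model, `predict_dementia_probability` produces a
per-epoch dementia probability for everyone alive and not yet
ascertained -- including participants lost to follow-up, whose vital
status is known through register linkage -- using each person's
empirical-Bayes posterior means (plug-in). Plug-in is the default rather
than posterior averaging for a numerical reason documented here:
averaging makes the log odds carry a posterior-width term that shrinks
as follow-up accumulates, which manufactures a spurious calendar drift
in the next step. `extract_calendar_trend` then regresses the log odds
of the predicted probability on sex, age, age squared, their
interactions and calendar time; because the lost-to-follow-up are back
in the risk set with predictions that extrapolate their observed
decline, the selective-attrition bias of the naive estimator is removed.
`adjust_trend_for_risk_factors` adds time-varying risk factors (last
observation carried forward after dropout) and reports the attenuation
`100 * (1 - beta_adj / beta_unadj)` of the calendar coefficient; the
risk factors also enter the event submodel, which is what allows the
predictions to carry their trend.

## Design choices in the joint model

* Two random effects (intercept, slope on current age in decades) rather
  than three: the age-slope loading equals age-at-entry plus time, so
  the two slope terms of the larger parameterisation collapse into one
  coefficient. With a random slope on time-since-entry instead, the
  model is misspecified against an age-driven latent process and its
  calendar fixed effect absorbs selection drift that propagates into the
  predictions.
* Start values come from the classic two-stage estimator (logistic fit
  with plug-in posterior-mean value and slope), which puts BFGS within a
  few dozen iterations of the optimum; the optimised marginal
  log-likelihood is checked against its start value in the tests.
* Probabilities at exactly 0 or 1 are clipped at `1e-6` before logit
  transforms, with a warning.

# The eight-state projection model

Living states are combinations of CVD, cognitive impairment without
dementia (CIND), dementia, and functional impairment: 1 healthy; 2 CVD;
3 CIND; 4 CIND+CVD; 5 functional impairment (no dementia); 6 dementia;
7 dementia+CVD; 8 functional impairment (no dementia)+CVD; plus two
absorbing death states (CVD, non-CVD). States 6-7 are the dementia
states and 5-8 the functionally impaired states; dementia implies
functional impairment by the case definition. Progression conventions:
no recovery from dementia, CVD is never lost; CIND and non-dementia
functional impairment may remit (both switches are configurable in
`allowed_transitions()`, since panel data genuinely show remission);
direct transitions 5 to 6 and 8 to 7 are allowed.

Calibration proceeds in five steps.

1. **Two-year transition probabilities** (`estimate_transition_probabilities`):
   wave pairs are pooled so each person contributes one observation per
   epoch observed; per destination state, a logistic model with age, sex,
   their interaction and the initial state (plus age squared and its sex
   interaction for the CIND destinations) is fitted, and its margins on
   the single-year age grid give the probabilities. The stay probability
   is the residual; below age 50 the off-diagonal entries taper smoothly
   to zero at 35 (the panel recruits at 50+, and incidence at these ages
   is negligible).
2. **Epoch-length conversion** (`two_year_to_one_year`):
   `TP = 1 - exp(log(1 - P)/2)`, the constant-hazard-within-epoch
   solution, with the algebraic inverse `P = 1 - (1 - TP)^2`.
3. **Starting prevalence** (`fit_starting_prevalence`): person-waves are
   pooled and attributed to the panel's mid-point year (2006); per-sex
   multinomial logistic curves in age and age squared give smooth
   single-year prevalences, tapering non-healthy states to zero at 35.
4. **State-specific mortality** (`estimate_state_mortality_odds` +
   `project_mortality`): per cause, the odds ratio of two-year death
   from each state (versus healthy, adjusted for age and sex); national
   cause-specific rates in five-year bands are extrapolated per stratum
   by a log-linear trend (the projector is a pluggable interface -- an
   age-period-cohort backend could be substituted) and interpolated to
   single ages by a monotone spline on the log rate. Rates convert to
   annual probabilities as `q = 1 - exp(-rate)`.
5. **Calendar-specific assembly** (`build_transition_set`): for each
   year, dementia- and CIND-incidence entries are scaled *on the odds
   scale* (matching the trend's definition as an OR) by the scenario's
   per-year factor; CVD-incidence entries by the relative change in the
   projected CVD mortality for the same stratum (incidence is assumed to
   decline in parallel with mortality, and is held constant after the
   freeze year in that sensitivity scenario); death entries are the
   state odds ratios applied to the year's projected rates, calibrated
   by a vectorised Newton solve so the starting-prevalence-weighted mean
   over states reproduces the population rate (mortality from every
   state changes in parallel); rows renormalise through the stay
   probability. The odds-scaling and epoch-length conversion do not
   commute exactly; the discrepancy is below `1e-3` for probabilities up
   to 0.25 and below `2.5e-3` at 0.3 under the ten-year cumulated
   factor, measured and asserted in the tests.

The engine (`project_population`) iterates annually: transitions, then
ageing by one year (100+ is an open band), then injection of the
entering 35-year-old cohort into the healthy state -- this ordering
keeps the entrants defined at exact age 35. No half-cycle correction is
applied; deaths belong to the year of the transition. Outputs are state
counts, dementia counts (states 6+7), crude 50+ and 65+ prevalence by
sex (the denominator age range is explicit, since the modelled
population starts at 35), age-standardised prevalence (weights: the
modelled population of the standard year, 2015 by default), deaths by
cause, and cohort life expectancy / disability-free life expectancy
(disability = states 5-8) with the last modelled year's probabilities
held beyond the horizon. Person conservation (entrants + initial
population = alive + cumulative deaths) holds to floating-point
accuracy and is asserted at `1e-8` in the tests; the transition kernel
is validated against direct matrix powers and the full engine against an
independently built age-structured operator.

# Scenarios and uncertainty

The scenario battery mirrors the conventional sensitivity set: the
estimated trend, fixed 2% and 1.1% relative annual declines, no decline,
and a variant freezing CVD incidence after 2014. Monte Carlo uncertainty
(`run_psa`) samples every calibrated coefficient vector (transition
logistics, state mortality odds, and the trend log-OR from its
CI-implied normal) from its estimated multivariate normal -- coefficient
level rather than probability level, so each draw's derived quantities
are internally consistent -- rebuilds the transition set, re-runs the
projection, and reports empirical 2.5/50/97.5 percentiles over 1000
draws by default. The sampling distribution for the parameters is a
choice (the estimators' asymptotic normality), documented here because
no canonical specification exists. A single seed drives the whole draw
stream; failed draws are logged, excluded, and more than 5% of them is
an error.

# The synthetic cohort generator

`generate_cohort` emulates the panel the analysis assumes: a core sample
of 11,400 recruited in 2002 at ages 50-89 with refreshment cohorts at
waves 3 (ages 50-55), 4 (50-74) and 6 (50-55), about 17,900 people in
all, observed biennially to 2012 with a 2014 follow-up wave used only
for transience. One latent cognitive factor per person (random intercept
and age-slope; fixed decline with age; education offsets) drives all
test scores (score = latent value + domain shift + noise); dementia
onset follows a per-epoch logistic hazard with age, sex, risk-factor and
calendar terms plus `alpha_value`/`alpha_slope` associations to the
latent trajectory, with the true per-year OR 0.973 by default; onset
accelerates decline and produces ADL impairment, proxy interviews with
informant scores, and accruing doctor diagnoses. Cause-specific
mortality is Gompertz in age with realistic English-level rates
(calibrated so period life expectancy at 65 is about 20/23 years for
men/women), multiplicative state excesses, and secular declines
(steeper for CVD and for men); CVD incidence declines in parallel with
CVD mortality. Dropout is a per-epoch logistic in the standardised
latent decline rate -- the informative-attrition mechanism the joint
model corrects; deaths remain observed after dropout (register linkage).
Two defaults deserve explanation:

* **Equilibrium prevalent cases.** Prevalent dementia is generated by
  running the same onset hazard over 13 pre-entry epochs with a
  survival-with-dementia thinning `exp(-0.45k)`, and people who would
  have died with dementia before recruitment are rejection-resampled
  (they could not appear in an alive sample). This puts the entry
  cross-section at selection equilibrium with respect to the latent
  trajectory. Without it, in-study ascertainment progressively depletes
  the low-cognition tail from an unselected starting distribution, which
  manufactures a spurious extra calendar decline that no estimator --
  however correct -- could be expected to remove.
* **Calibrated incidence.** The hazard intercept and sex effect are set
  so that ascertained incidence at 2010 is about 14-15 per 1000
  person-years in men and 16-17 in women aged 50+, the conventional
  magnitudes for an English panel of this design.

The generator's dropout magnitude (log-odds increment 0.9 per SD of
latent decline, baseline 7% per epoch) is illustrative rather than
calibrated -- no published quantification of the real mechanism exists
-- and is chosen to make the naive estimator's attrition bias clearly
visible (about -0.01 to -0.02 on the OR scale) while remaining within
plausible attrition totals (~30% ever lost over six waves).

What the generator does *not* emulate: geographic or household
structure, survey weights (a unit weight column is emitted for interface
compatibility), birth-cohort effects in cognition, learning effects
across repeated testing, item-level test behaviour, and -- importantly
for the projections -- the age-structure bulges of the real population
(the default population grid is smooth, built from cohort survival under
the generator's own rates with a historical-trend correction). Passing
tests therefore show that the estimators and the engine are correct
under the stated mechanisms at realistic magnitudes, not that real-data
projections would be numerically reproduced; in particular the absolute
projected counts are not comparable to published national figures, whose
growth is driven by demographic waves the synthetic population lacks.

# Validation design and problem sizes

The test suite validates each module against independent oracles (hand
computations, closed forms, matrix powers, construction identities) and
the pipeline end-to-end against the generator's ground truth. The
dropout-correction study runs twenty full replicates at the default
study size (~17,900 people, six waves, true OR 0.973, informative
dropout on): the joint-model-corrected OR must average within 0.01 of
the truth and be strictly less biased than the naive estimator, and the
competing-risks estimate must be steeper than the naive one on average.
Smaller fixtures (a ~3,300-person cohort) back the engine, calibration
and Monte Carlo tests; the sensitivity analysis is exercised with 1000
draws on a shortened horizon. These sizes are the package's chosen
trade-off between Monte Carlo error and runtime and are asserted as
such in the tests.

# Known limitations

* The joint model profiles the longitudinal parameters rather than
  maximising all parameters simultaneously; with attrition that depends
  on the random effects, the longitudinal-stage estimates retain a
  small partial-likelihood bias (visible as a spurious calendar
  coefficient of order +0.003 SD/year in the mixed model), which
  propagates a fraction of a percentage point into the extracted trend.
* The marginal (population-average) incidence trend in an equilibrium
  population whose hazard declines differs from the conditional per-person
  trend by a composition term (depletion weakens as the hazard falls);
  the naive estimator targets the former, the joint pipeline the latter.
  The acceptance tolerance of 0.01 on the OR absorbs both effects.
* Severity within states is averaged (one transition probability per
  stratum), CIND/functional-impairment remission is a modelling choice
  the data support but the state structure does not force, and the
  mortality projector deliberately ignores cohort effects.
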