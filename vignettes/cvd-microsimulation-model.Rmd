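---
title: "The CVD microsimulation policy model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CVD microsimulation policy model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`cvdmicrosim` is an individual-level cardiovascular disease (CVD) policy
model. Each person is simulated one annual cycle at a time, from their entry
age until death or age 110, through seven competing first-occurrence
endpoints: myocardial infarction (MI), stroke, coronary revascularisation
(CRV), incident cancer, incident diabetes, vascular death and nonvascular
death. Within each cycle the endpoints are drawn in a fresh uniformly random
order; an endpoint already in a person's history is skipped (the model
simulates first occurrences only); each drawn endpoint fires with its annual
event probability given the state as updated so far within the cycle; a death
ends the cycle. Survivors then age one year, year-of-event flags roll over to
prior-years, and event durations increment. Age and event histories therefore
feed back into all subsequent risks in a time-dependent way: a same-year MI
raises the same-year stroke and vascular-death hazards through the
year-of-event coefficients, which are distinct from (and typically much
larger than) the subsequent-years coefficients.

### Risk equations

Each endpoint's annual hazard follows a proportional-hazards form with a
Gompertz baseline on current age:

$$
h(t) = \exp\!\big(\beta_0 + s\,(a_t - a_0) + x_t'\beta + c\big),
$$

where $a_t$ is current age, $a_0$ the age centring constant, $x_t$ the
covariate vector resolved from the baseline profile and the time-updated
state, and $c$ an additive calibration shift on the log baseline. The
Gompertz family (log hazard linear in age) is the natural choice on an age
timescale for mortality-type endpoints and makes the annual time-dependence
of the baseline exact; the baseline is pluggable in principle, but Gompertz
is the implemented default. Separate equations serve individuals without and
with CVD history at entry; incident cancer and incident diabetes use single
equations pooled across both populations. Population routing is fixed at
entry: a primary-prevention person who suffers an MI during simulation stays
on the primary-prevention equations, with the incident event acting through
the event-history covariates — mirroring how such equations are fitted.

Covariate names are drawn from a single shared registry
(`covariate_registry()`) used identically by the simulation engine, the
utility model, the estimation module and the synthetic-data generators, so a
coefficient file cannot silently reference a covariate the simulator resolves
differently. Continuous covariates are centred at constants carried inside
the coefficient file itself, making files self-describing. Notable registry
semantics:

* `mi_this_year` / `mi_prior_years` (and the stroke and CRV analogues)
  encode the event-phase structure; the year-of-event value applies for
  exactly one annual cycle.
* `hba1c_nondiab` contributes only while a person has no diagnosed diabetes;
  incident diabetes switches it off and the diabetes-duration bands
  (`diabetes_lt10`, `diabetes_ge10`, split at 10 years) on.
* A protective CRV effect on vascular death is an ordinary negative
  coefficient; nothing is special-cased.

### Discretization

Hazards are treated as constant within each annual cycle and converted to
event probabilities by $p = 1 - e^{-h}$. This makes the one-year marginal of
the discrete engine agree with a continuous-time competing-risks process to
second order in the hazards: for two competing hazards $h_1, h_2$, both the
random-order sequential-Bernoulli scheme (averaged over orders) and the
continuous-time race give $P = h_1 - h_1(h_1 + h_2)/2 + O(h^3)$. The random
event order is what buys this: an event fired earlier in the cycle exposes
later endpoints to its boosted hazards for the whole cycle with probability
one half, matching the continuous process's expected half-year of boosted
exposure. The package carries an independent continuous-time implementation
(`generate_followup()`, below) and tests the engine against it.

### Life years, QALYs and utilities

EQ-5D utility is predicted annually by a linear model over the same registry
(intercept plus decrements/increments), clamped to the EQ-5D-3L range
$[-0.594, 1]$ (the worst describable health state to full health). MI and
stroke carry a year-of-event decrement for exactly one cycle and a
subsequent-years decrement afterwards; prevalent entry history counts as the
subsequent phase; the diabetes decrement switches at 10 years of duration;
cancer carries a single any-history decrement. The year-of-event convention
(exactly one cycle) was a genuinely open choice; it was adopted because it
mirrors the risk-equation phase structure exactly and keeps the two models'
covariate resolution identical.

Life years count complete cycles survived; with the half-cycle correction
(on by default, standard state-transition-model practice) the death year
contributes half a year and half its annual utility. QALYs accumulate
utility-weighted exposure under the same convention. Discounting is off by
default (rate 0) and available as a configuration knob. The per-cycle
exposure and utility streams can be retained (`audit = TRUE`) and the tests
verify the accounting identities against them.

### Random numbers and common-random-number contrasts

Every draw derives from the master seed through per-(replicate, cycle)
substreams, with uniforms indexed by (person, endpoint). Runs are therefore
bitwise reproducible, and two scenarios simulated under the same seed consume
identical uniforms: a treatment that only multiplies hazards by factors
$\le 1$ can change an outcome only by removing events, which makes
treatment-control contrasts low-variance and, when all event-history
coefficients are nonnegative, pathwise dominant. Uptake levels are nested
under the same coupling (the half-uptake treated set is a subset of the
full-coverage one), so gains scale linearly in uptake by construction plus a
random-subset term.

## Estimation, calibration, validation

`fit_risk_equation()` fits the Gompertz PH model by maximum likelihood
through its person-period (piecewise-exponential) representation: follow-up
is episode-split at every year boundary and additionally at event times, so
time-updated history covariates are exact within episodes, and a Poisson
regression with a log-exposure offset is fitted by `stats::glm`. The
Gompertz age term uses the episode midpoint age (the within-episode
approximation error is $O(s^2/24)$ for slope $s$ on one-year episodes,
negligible at the slopes involved). An intercept-only fit recovers
`log(events / person-years)` exactly. Constant covariates are dropped with a
warning, never silently zeroed.

`bootstrap_ensemble()` draws person-level resamples with replacement.
Because a resampled person contributes exactly their original episode rows,
the episode split is computed once and each replicate reduces to a Poisson
fit on a row-index resample, keeping ensembles of hundreds of coefficient
sets cheap. Replicate 0 is reserved for the point estimate; probabilistic
sensitivity analysis (`run_psa()`) reports empirical 2.5/97.5 percentile
intervals across replicates 1..B.

`observed_cumulative_incidence()` estimates incidence in the Aalen-Johansen
form (via `survival::survfit` on a multi-state factor), treating death from
other causes as a competing risk. This matches the estimand the simulation
produces — model-simulated incidence is inherently competing-risk — and is
the default everywhere; the naive 1-KM variant is available behind a flag
because published validation plots sometimes use it.

`calibrate_model()` chooses additive intercept shifts on the log baselines to
minimize the summed squared difference between simulated and observed
cumulative incidence over the follow-up years. The search iterates
multiplicative updates $c \leftarrow c + \log(\mathrm{obs}_H/\mathrm{sim}_H)$
at the final year with common random numbers across iterations, keeps the
best shifts visited (so post-calibration discrepancy never exceeds
pre-calibration), and reports both. Calibration is per endpoint and — where
the target cohort contains both populations — per population; slope shifts
are left at zero by default (intercept-only recalibration is the standard,
auditable choice, and suffices for the known-scaling recovery the tests
demand). Self-calibration is a fixed point up to Monte Carlo noise.

## The synthetic-data module

The generators make the package fully testable without any data access:

* `generate_cohort()` draws profiles from configurable marginals whose
  defaults approximate the primary-prevention column of a large contemporary
  UK cohort's baseline table: 44% male, age mean 56 (SD 8.1) truncated to
  40–70, LDL 3.6 (0.82) mmol/L, HbA1c 35.8 (6.2) mmol/mol, deprivation
  quintile shares 37/20/16/14/13%, 4.9% prevalent diabetes, 7.4% prior
  cancer, and so on. An optional Gaussian copula induces dependence between
  the continuous biomarkers; the default is independence. These defaults are
  the package's study conditions and are not tuned per test.
* `generate_followup()` is the engine's oracle: a continuous-time
  competing-risks sampler (cause-specific exponential races within each
  year, state updating mid-year at event times) that shares no
  event-sampling code with the engine. Cross-implementation agreement of
  lifetime cause-of-death distributions and per-endpoint incidence is an
  acceptance property.
* `generate_utility_survey()` emits survey-style utility records (linear
  prediction plus Gaussian noise, clamped to $[-0.594, 1]$).
* `synthetic_true_model()` is the fixture coefficient set (also shipped as
  `extdata/synthetic_coefficients.json`, labelled synthetic): modest
  Gompertz baselines with age slopes 0.09–0.10/year on the death endpoints,
  event-history hazard ratios largest in the year of event, a protective
  CRV effect on vascular death, a deprivation log hazard ratio of
  $\log 1.15$ per quintile step on stroke, incident diabetes and both
  deaths, and the utility decrement structure (MI 0.10/0.07, stroke
  0.09/0.13, diabetes 0.04/0.08 split at 10 years, cancer 0.03). The values
  mirror the qualitative structure of published equation sets without
  claiming any fitted magnitudes.

What passing tests on these data do and do not show: the generators draw
covariates (mostly) independently, produce exactly Gompertz-PH hazards, and
contain no measurement error, missing data (beyond the explicit "missing"
physical-activity category), secular trends, or model misspecification. Tests
therefore verify that the machinery is correct — discretization,
competing-risk accounting, estimation, calibration, standardization — not
that any particular coefficient set predicts real populations well. Real use
requires externally fitted and calibrated coefficient files.

## Treatment scenarios

Statin eligibility follows the guideline rule: with CVD history,
atorvastatin 80 mg/day (20 mg when eGFR < 60 mL/min/1.73m²); without, 20
mg/day when 10-year CVD risk ≥ 10%, or with type 1 diabetes, eGFR < 60, or
albuminuria. eGFR is taken from the profile or derived from creatinine, age
and sex by the CKD-EPI 2021 race-free equation (recorded in scenario
metadata). The 10-year risk can come from an external score supplied in the
cohort file, from the model's own Monte-Carlo estimate
(`ten_year_mve_risk()`), or from a fast deterministic cumulative-hazard
score (`ten_year_risk_score()`) used for whole-cohort screening.

Treatment effects are deliberately required configuration with no shipped
defaults: a regimen lowers LDL by a configured fraction of baseline, and
each affected vascular endpoint's hazard is multiplied by a configured rate
ratio per mmol/L raised to the achieved reduction. The example YAML marks
its numbers as placeholders. Treatment is assigned once at entry and held
lifelong; by default it does not touch incident diabetes or any nonvascular
endpoint. The effect enters *only* through these hazard multipliers: the
`ldl` covariate in the risk equations keeps its baseline value (the achieved
LDL is tracked for audit), because letting the reduction act both through
the covariate and through the rate ratios would double-count it.

`run_scenario()` assesses eligibility at entry, draws a treated indicator
once per person per replicate with quintile-specific uptake, simulates the
treated and no-statin counterfactual arms under common random numbers, and
reports life years and QALYs gained per 1000 by sex × age band × deprivation
quintile together with the fraction eligible.

## Population summaries

`summarize_by_category()` averages per-person outcomes over any partition;
`standardize_means()` reweights sex × age band × quintile cell means to a
reference population (weights normalized; positive-weight cells without
estimates are an error unless explicitly dropped and renormalized);
`gradient_gap()` reports quintile 1 minus quintile 5 at 10-year, 20-year and
lifetime horizons. The cohort's deprivation quintile is mapped one-to-one by
rank onto the reference population's quintile dimension — the two may come
from different deprivation indices, and rank alignment is the only mapping
that needs no external concordance table. Age bands default to 5-year bands
over 40–70 with open ends.

## Numerical choices and problem sizes

* Probabilities use `-expm1(-h)`; a hazard of numerical infinity yields
  probability 1 without overflow, and non-finite hazards raise a typed
  error pointing at the coefficient file.
* Permutations are drawn by rank of uniform keys (radix order over stacked
  columns), giving exact uniform orders at vector speed.
* Seeds derive from the master seed by an integer mixing function kept
  inside 32-bit range; all generators and runs are deterministic per seed.
* The test and acceptance runs use cohorts of 1,000–200,000 persons and 1–5
  replicates per person, chosen so each statistical check has at least
  ~2.5–3 standard errors of headroom at its stated tolerance while the full
  suite stays a desktop-scale run; the packaged defaults
  (500 replicates per person) reflect production use.

## Known limitations

* First occurrences only: no recurrent MI/stroke, no event severity.
* Population routing is fixed at entry; a primary-prevention person is never
  re-routed to the secondary-prevention equations after an incident event
  (the event-history covariates carry the risk increase instead).
* OLS utility fitting ignores the ceiling at 1; with noise SDs large
  relative to the headroom, censoring biases the intercept slightly (the
  survey generator's recovery tests use noise where this is negligible, and
  the limitation matters for real survey fits near full health).
* Calibration searches intercept shifts only by default; a slope shift field
  exists but no automated search over it is provided.
* The deterministic screening score ignores event-history feedback and
  competing nonvascular mortality; it is a screening device, not a
  replacement for the Monte-Carlo risk.
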