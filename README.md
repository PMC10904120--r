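# cvdmicrosim

An individual-level cardiovascular disease (CVD) microsimulation policy
model for R.

Risk scores such as QRISK estimate one outcome over a fixed window. A policy
model instead projects each person's whole remaining life course — competing
disease events, survival and quality of life — so that long-term outcomes
and treatment policies can be compared across population subgroups.
`cvdmicrosim` implements such a model as a reusable simulator for
biostatisticians and health economists:

* **Annual-cycle competing-event engine.** Seven endpoints (myocardial
  infarction, stroke, coronary revascularisation, incident cancer, incident
  diabetes, vascular and nonvascular death) simulated in a fresh random
  order each year until death or age 110, with event histories feeding back
  into subsequent risks (year-of-event vs later-years effects, diabetes
  duration bands, HbA1c effects confined to those without diabetes).
* **Gompertz proportional-hazards risk equations.** Annual hazard
  $h = \exp(\beta_0 + s\,(\text{age}-a_0) + x'\beta + c)$, discretized as
  $p = 1-e^{-h}$; separate equations for people without and with CVD
  history; self-describing JSON coefficient files over a shared covariate
  registry.
* **EQ-5D utilities and QALYs.** A linear utility model with the
  event-phase decrement structure, clamped to $[-0.594, 1]$, accumulated
  into (optionally discounted) QALYs with a half-cycle correction.
* **Estimation, calibration, validation.** Episode-split person-period
  Poisson fitting of the risk equations from individual follow-up data,
  fast person-level bootstrap ensembles, baseline recalibration to observed
  Aalen–Johansen cumulative incidence, and predicted-vs-observed validation
  reports by subgroup.
* **Treatment policy analysis.** Guideline statin eligibility (10-year risk
  threshold, type 1 diabetes, eGFR, albuminuria; 80 mg vs 20 mg by CVD
  history and kidney function), LDL-mediated hazard multipliers, and
  full-coverage vs real-world-uptake scenarios run against a no-treatment
  counterfactual with common random numbers.
* **Population summaries.** Direct standardization of life expectancy and
  QALYs to a reference population by sex × age band × deprivation quintile,
  and quintile-gap (inequality) reports.
* **Synthetic data.** Generators for cohorts, follow-up data from known
  true hazards (an independent continuous-time oracle used to test the
  engine), utility surveys and reference weights — the package is fully
  testable offline.

## Worked example

```r
library(cvdmicrosim)

model  <- read_coefficients(system.file("extdata",
          "synthetic_coefficients.json", package = "cvdmicrosim"))
cohort <- generate_cohort(5000, seed = 1)

summ <- run_microsimulation(cohort, model,
                            sim_config(replicates = 5, master_seed = 1))
summ$aggregate$mean_life_years
#> [1] 23.43698
summ$aggregate$mean_qalys
#> [1] 18.92999
round(incidence_curve(summ, "mi", c(5, 10)), 4)
#>      5     10 
#> 0.0135 0.0298
```

A cohort with mean entry age 56 is projected to live a further 23.4 years on
average (18.9 quality-adjusted), and 3.0% suffer a first MI within ten
years. Standardizing to a reference population and taking quintile gaps:

```r
tab <- summarize_by_category(summ, cohort,
                             by = c("sex", "age_band", "quintile"))
std <- standardize_means(tab, generate_reference_weights(),
                         margin = "quintile", missing_policy = "drop")
round(gradient_gap(std)$life_years_gap, 2)
#> [1] 4.48
```

Under the packaged synthetic equations (deprivation log hazard ratio
log 1.15 per quintile step on stroke, diabetes and both deaths), the least
deprived quintile outlives the most deprived by about 4.5 standardized life
years. Treatment scenarios need explicit effect parameters (none are
hard-coded); see `inst/extdata/example_scenario.yaml` for the config shape
and `run_scenario()` for the common-random-numbers contrast.

The numbers above are produced by the packaged *synthetic* coefficient set,
which mirrors the qualitative structure of published CVD equations without
claiming fitted magnitudes; real analyses require externally estimated and
calibrated coefficient files (`fit_all_equations()`, `calibrate_model()`).

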