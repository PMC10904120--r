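make_recovery_model <- function() {
  flat_model(hazards = c(nonvascular_death = 0.02),
             slopes = c(nonvascular_death = 0.09),
             coefs = list(nonvascular_death = c(male = 0.5,
                                                smoke_current = 0.3)))
}

test_that("Gompertz PH fitting recovers known parameters within 3 SE", {
  truth <- make_recovery_model()
  co <- generate_cohort(5000, seed = 61)
  ipd <- generate_followup(co, truth, max_years = 10, seed = 62)
  fit <- fit_risk_equation(ipd, "nonvascular_death", "no_cvd",
                           covariates = c("male", "smoke_current"))
  expect_lt(abs(fit$coefficients[["male"]] - 0.5) / fit$se[["male"]], 3)
  expect_lt(abs(fit$coefficients[["smoke_current"]] - 0.3) /
              fit$se[["smoke_current"]], 3)
  expect_lt(abs(fit$baseline$age_slope - 0.09) / fit$se[["age_current"]], 3)
  expect_lt(abs(fit$baseline$log_hazard_intercept - log(0.02)) /
              fit$se[["(Intercept)"]], 3)
})

test_that("the null model recovers the event rate in closed form", {
  cs <- flat_model(hazards = c(nonvascular_death = 0.03))
  co <- generate_cohort(3000, seed = 44)
  ipd <- generate_followup(co, cs, max_years = 8, seed = 45)
  fit <- fit_risk_equation(ipd, "nonvascular_death", "no_cvd",
                           include_age = FALSE)
  n_events <- sum(ipd$events$endpoint == "nonvascular_death")
  py <- sum(ipd$end_time)
  # intercept-only person-period Poisson MLE is exactly log(events / exposure)
  expect_equal(fit$baseline$log_hazard_intercept, log(n_events / py),
               tolerance = 1e-6)
  expect_lt(abs(log(n_events / py) - log(0.03)), 3 / sqrt(n_events))
})

test_that("constant covariates are dropped with a warning, not silently zeroed", {
  cs <- flat_model(hazards = c(nonvascular_death = 0.05))
  co <- generate_cohort(400, seed = 5,
                        config = cohort_config(ethnicity = c(white = 1,
                                                             black = 0,
                                                             south_asian = 0,
                                                             other = 0)))
  ipd <- generate_followup(co, cs, max_years = 5, seed = 6)
  expect_warning(
    fit <- fit_risk_equation(ipd, "nonvascular_death", "no_cvd",
                             covariates = c("male", "eth_black")),
    "eth_black")
  expect_identical(attr(fit, "dropped"), "eth_black")
  expect_false("eth_black" %in% names(fit$coefficients))
})

test_that("fitting an endpoint with no events is an estimation error", {
  cs <- flat_model(hazards = c(nonvascular_death = 0.05))
  co <- generate_cohort(100, seed = 9)
  ipd <- generate_followup(co, cs, max_years = 3, seed = 10)
  expect_error(fit_risk_equation(ipd, "stroke", "no_cvd"),
               class = "cvd_estimation_error")
})

test_that("observed cumulative incidence matches a hand-computed curve", {
  co <- generate_cohort(4, seed = 1)
  # events at years 0.9 and 1.9; censored at 3 and 4; no competing deaths,
  # so Aalen-Johansen reduces to 1 - KM
  ev <- data.frame(person_id = co$person_id[1:2], endpoint = "mi",
                   time = c(0.9, 1.9))
  ipd <- followup_data(co, ev, end_time = c(0.9, 1.9, 3, 4))
  aj <- observed_cumulative_incidence(ipd, "mi", 2)
  km <- observed_cumulative_incidence(ipd, "mi", 2, method = "one-minus-km")
  expect_equal(unname(aj), c(0.25, 0.50))
  expect_equal(aj, km)
  # no events: flat zero; all events in year one: jumps to one
  ipd0 <- followup_data(co, ev[0, ], end_time = rep(5, 4))
  expect_equal(unname(observed_cumulative_incidence(ipd0, "mi", 3)),
               rep(0, 3))
  ev1 <- data.frame(person_id = co$person_id, endpoint = "mi",
                    time = c(0.2, 0.4, 0.6, 0.8))
  ipd1 <- followup_data(co, ev1, end_time = rep(5, 4))
  expect_equal(unname(observed_cumulative_incidence(ipd1, "mi", 2)),
               c(1, 1))
})

test_that("competing deaths separate the Aalen-Johansen and 1-KM estimands", {
  cs <- flat_model(hazards = c(mi = 0.03, nonvascular_death = 0.10))
  co <- generate_cohort(4000, seed = 71)
  ipd <- generate_followup(co, cs, max_years = 15, seed = 72)
  aj <- observed_cumulative_incidence(ipd, "mi", 15)
  km <- observed_cumulative_incidence(ipd, "mi", 15, method = "one-minus-km")
  # 1-KM overstates incidence in the presence of competing mortality
  expect_gt(km[[15]], aj[[15]])
  # AJ matches the closed-form cause-specific cumulative incidence
  want <- 0.03 / 0.13 * (1 - exp(-0.13 * 15))
  expect_lt(abs(aj[[15]] - want), 3 * sqrt(want * (1 - want) / 4000))
})

test_that("bootstrap ensembles are deterministic and complete", {
  truth <- make_recovery_model()
  co <- generate_cohort(800, seed = 81)
  ipd <- generate_followup(co, truth, max_years = 8, seed = 82)
  spec <- list(list(endpoint = "nonvascular_death", population = "no_cvd",
                    covariates = "male"))
  e1 <- bootstrap_ensemble(ipd, spec, B = 10, seed = 7, base = truth)
  e2 <- bootstrap_ensemble(ipd, spec, B = 10, seed = 7, base = truth)
  expect_length(e1, 10)
  expect_equal(e1, e2)
  expect_identical(vapply(e1, function(s) s$replicate_id, 0L), 1:10)
  # every replicate remains a complete, simulatable coefficient set
  expect_no_error(run_microsimulation(co[1:2, ], e1[[3]],
                                      sim_config(replicates = 1, horizon = 2)))
})

test_that("self-calibration is a fixed point and never worsens the objective", {
  cs <- flat_model(hazards = c(mi = 0.004, stroke = 0.002,
                               vascular_death = 0.003,
                               nonvascular_death = 0.02))
  co <- generate_cohort(6000, seed = 91)
  ipd <- generate_followup(co, cs, max_years = 10, seed = 92)
  cal <- calibrate_model(cs, ipd, horizon = 10,
                         endpoints = c("mi", "nonvascular_death"),
                         config = sim_config(replicates = 2, horizon = 10,
                                             master_seed = 3),
                         max_iter = 4, tol = 0.02)
  expect_true(all(abs(cal$report$intercept_shift) < 0.15))
  expect_true(all(cal$report$discrepancy_post <=
                    cal$report$discrepancy_pre + 1e-12))
})

test_that("calibration recovers a known hazard scaling", {
  cs <- flat_model(hazards = c(mi = 0.004, nonvascular_death = 0.02))
  doubled <- flat_model(hazards = c(mi = 0.008, nonvascular_death = 0.04))
  co <- generate_cohort(6000, seed = 93)
  target <- generate_followup(co, doubled, max_years = 10, seed = 94)
  cal <- calibrate_model(cs, target, horizon = 10,
                         endpoints = c("mi", "nonvascular_death"),
                         config = sim_config(replicates = 2, horizon = 10,
                                             master_seed = 4),
                         max_iter = 5, tol = 0.02)
  sh <- cal$report$intercept_shift
  expect_true(all(abs(sh - log(2)) < 0.2))
  expect_true(all(cal$report$discrepancy_post <=
                    cal$report$discrepancy_pre + 1e-12))
})

test_that("validation reports per-endpoint horizons and partition-additive counts", {
  cs <- flat_model(hazards = c(mi = 0.01, diabetes = 0.01,
                               nonvascular_death = 0.02))
  co <- generate_cohort(1500, seed = 96)
  ipd <- generate_followup(co, cs, max_years = 12, seed = 97)
  v <- validate_model(cs, ipd, subgroups = "sex", horizon = 12,
                      endpoint_horizons = list(diabetes = 8),
                      config = sim_config(replicates = 2, master_seed = 5,
                                          horizon = 12))
  expect_equal(max(v$year[v$endpoint == "diabetes"]), 8)
  expect_equal(max(v$year[v$endpoint == "mi"]), 12)
  # subgroup event counts add up to the whole-cohort count
  at12 <- v[v$endpoint == "mi" & v$year == 12, ]
  expect_equal(at12$n_events[at12$subgroup == "overall"],
               sum(at12$n_events[at12$subgroup != "overall"]))
  # empty subgroups are skipped, not errors
  v2 <- validate_model(cs, ipd,
                       subgroups = list(none = rep(FALSE, nrow(co))),
                       horizon = 3,
                       config = sim_config(replicates = 1, master_seed = 5,
                                           horizon = 3))
  expect_identical(attr(v2, "skipped"), "none")
})
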