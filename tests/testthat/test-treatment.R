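example_effect <- function() {
  treatment_effect(
    ldl_reduction_fraction = c(atorva20 = 0.4, atorva80 = 0.5),
    rate_ratio_per_mmol = c(mi = 0.8, stroke = 0.85, crv = 0.8,
                            vascular_death = 0.9))
}

test_that("statin assignment follows the guideline rule exactly", {
  rule <- statin_rule()
  p <- typical_profile()          # no CVD history, eGFR well above 60
  expect_equal(assign_statin(p, risk = 12.6, rule), "atorva20")
  expect_equal(assign_statin(p, risk = 9.9, rule), "none")
  expect_equal(assign_statin(p, risk = 10.0, rule), "atorva20")
  # qualifying conditions override a low risk score
  t1d <- reference_profile(diabetes = "type1", diabetes_years = 5)
  expect_equal(assign_statin(t1d, risk = 2, rule), "atorva20")
  alb <- reference_profile(); alb$albuminuria <- 1L
  expect_equal(assign_statin(alb, risk = 2, rule), "atorva20")
  low_gfr <- reference_profile(); low_gfr$egfr <- 45
  expect_equal(assign_statin(low_gfr, risk = 2, rule), "atorva20")
  # CVD history: 80mg, downgraded to 20mg below the eGFR threshold
  cvd <- reference_profile(cvd_mi = 1L)
  expect_equal(assign_statin(cvd, risk = NA, rule), "atorva80")
  cvd$egfr <- 50
  expect_equal(assign_statin(cvd, risk = NA, rule), "atorva20")
  # primary prevention without any risk source is an error
  expect_error(assign_statin(p, risk = NULL, rule),
               "score", class = "cvd_config_error")
})

test_that("eGFR is derived from creatinine when absent", {
  p <- reference_profile(age = 75, sex = "female", creatinine = 130)
  e <- egfr_ckdepi(130, 75, "female")
  expect_lt(e, 60)
  expect_equal(assign_statin(p, risk = 2), "atorva20")
})

test_that("treatment effects are LDL-mediated hazard multipliers", {
  eff <- treatment_effect(
    ldl_reduction_fraction = c(atorva20 = 0.5, atorva80 = 0.5),
    rate_ratio_per_mmol = c(mi = 0.8))
  p <- reference_profile(ldl = 4)   # reduction = 2 mmol/L
  lm <- apply_treatment(p, "atorva20", eff)
  expect_equal(unname(exp(lm[1, "mi"])), 0.8^2, tolerance = 1e-12)
  expect_equal(unname(lm[1, setdiff(colnames(lm), "mi")]), rep(0, 6))
  expect_equal(unname(attr(lm, "ldl_current")), 2)
  # no regimen, or zero reduction, is the identity
  expect_equal(unname(apply_treatment(p, "none", eff)), matrix(0, 1, 7),
               ignore_attr = TRUE)
  eff0 <- treatment_effect(
    ldl_reduction_fraction = c(atorva20 = 0, atorva80 = 0),
    rate_ratio_per_mmol = c(mi = 0.8))
  expect_equal(unname(apply_treatment(p, "atorva20", eff0)), matrix(0, 1, 7),
               ignore_attr = TRUE)
  expect_error(apply_treatment(p, "simva40", eff), class = "cvd_config_error")
  # invariant violations are configuration errors
  expect_error(treatment_effect(c(atorva20 = 1.2, atorva80 = 0.5),
                                c(mi = 0.8)), class = "cvd_config_error")
  expect_error(treatment_effect(c(atorva20 = 0.4, atorva80 = 0.5),
                                c(mi = 1.3)), class = "cvd_config_error")
  expect_error(treatment_effect(c(atorva20 = 0.4, atorva80 = 0.5),
                                c(cancer = 0.8)), class = "cvd_config_error")
})

test_that("eligibility fraction matches a hand count on a toy cohort", {
  co <- do.call(rbind, lapply(1:10, function(i)
    as.data.frame(reference_profile())))
  co$person_id <- sprintf("t%02d", 1:10)
  co$ten_year_cvd_risk <- c(2, 5, 9.9, 10, 12, 15, 3, 4, 20, 1)
  co$cvd_mi[7] <- 1L
  co$diabetes[8] <- "type1"; co$diabetes_years[8] <- 3
  co <- validate_cohort(co)
  sc <- run_scenario(co, flat_model(hazards = c(nonvascular_death = 0.02)),
                     statin_rule(), example_effect(), uptake = 1,
                     config = sim_config(replicates = 1, master_seed = 1,
                                         horizon = 5))
  # hand count: risks >= 10 (rows 4,5,6,9), CVD history (7), T1DM (8)
  expect_identical(which(sc$eligible), c(4L, 5L, 6L, 7L, 8L, 9L))
  expect_equal(sum(sc$summary$fraction_eligible * sc$summary$n), 6)
})

test_that("zero uptake gives exactly zero gain under common random numbers", {
  co <- generate_cohort(50, seed = 23)
  sc <- run_scenario(co, synthetic_true_model(), statin_rule(),
                     example_effect(), uptake = 0,
                     config = sim_config(replicates = 2, master_seed = 9,
                                         horizon = 20))
  expect_equal(sc$person$ly_gain, rep(0, 50))
  expect_equal(sc$person$qaly_gain, rep(0, 50))
})

test_that("treatment dominates pathwise and full coverage dominates partial uptake", {
  # all event-history effects nonnegative and rate ratios <= 1, so the CRN
  # coupling makes every per-person gain nonnegative
  cs <- flat_model(hazards = c(mi = 0.01, stroke = 0.004,
                               vascular_death = 0.006,
                               nonvascular_death = 0.02),
                   coefs = list(vascular_death = c(mi_this_year = 1.2,
                                                   mi_prior_years = 0.6)),
                   utility = 0.85,
                   qol_coefs = c(mi_subsequent = -0.07))
  co <- generate_cohort(400, seed = 24)
  co$ten_year_cvd_risk <- rep(15, 400)  # everyone eligible
  co <- validate_cohort(as.data.frame(co))
  cfg <- sim_config(replicates = 2, master_seed = 13)
  full <- run_scenario(co, cs, statin_rule(), example_effect(), uptake = 1,
                       config = cfg)
  half <- run_scenario(co, cs, statin_rule(), example_effect(), uptake = 0.5,
                       config = cfg)
  expect_true(all(full$person$ly_gain >= -1e-12))
  expect_true(all(full$person$qaly_gain >= -1e-12))
  # nested uptake coupling: the half-uptake treated set is a subset, so the
  # per-category gains cannot exceed full coverage
  m <- merge(full$summary, half$summary,
             by = c("sex", "age_band", "quintile"), suffixes = c("_f", "_h"))
  expect_true(all(m$ly_gained_per_1000_f >= m$ly_gained_per_1000_h - 1e-9))
  # per-person: half-uptake gain is exactly the full gain or exactly zero
  z <- abs(half$person$ly_gain) < 1e-15 |
    abs(half$person$ly_gain - full$person$ly_gain) < 1e-12
  expect_true(all(z))
})

test_that("uptake maps must cover every quintile present", {
  co <- generate_cohort(10, seed = 25)
  expect_error(
    run_scenario(co, synthetic_true_model(), statin_rule(), example_effect(),
                 uptake = c("1" = 0.5, "2" = 0.5),
                 config = sim_config(replicates = 1, horizon = 2)),
    "quintile", class = "cvd_config_error")
})
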