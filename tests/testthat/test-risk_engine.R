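test_that("linear predictor matches an independent dot product over the registry", {
  cs <- synthetic_true_model()
  co <- generate_cohort(40, seed = 3)
  st <- new_sim_state(co)
  # age some people, plant some incident events
  st$current_age <- st$current_age + 4
  st$flags[1:5, "mi"] <- 1L
  st$flags[6:10, "mi"] <- 2L
  st$flags[6:10, "stroke"] <- 1L
  st$flags[11:15, "diabetes"] <- 2L
  st$diabetes_duration[11:15] <- c(1, 3, 9, 11, 14)
  for (key in c("vascular_death.no_cvd", "stroke.no_cvd", "diabetes.pooled")) {
    eq <- cs$equations[[key]]
    got <- linear_predictor(co, st, eq, cs$centring)
    # brute-force oracle: resolve one covariate at a time and accumulate
    want <- numeric(nrow(co))
    for (nm in names(eq$coefficients)) {
      v <- resolve_covariates(nm, co, st, cs$centring)[, 1]
      want <- want + v * eq$coefficients[[nm]]
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("reference-level profile with empty history has linear predictor zero", {
  cs <- synthetic_true_model()
  p <- reference_profile()
  st <- new_sim_state(p)
  lp <- linear_predictor(p, st, cs$equations[["mi.no_cvd"]], cs$centring)
  expect_equal(lp, 0)
})

test_that("event-history terms select the year-of-event vs subsequent coefficient", {
  eq <- risk_equation("vascular_death", "no_cvd", log(0.01),
                      coefficients = c(mi_this_year = 0.9,
                                       mi_prior_years = 0.4))
  p <- reference_profile()
  st <- new_sim_state(p)
  st$flags[1, "mi"] <- 1L
  expect_equal(linear_predictor(p, st, eq), 0.9)
  h_this <- annual_hazard(p, st, eq)
  st$flags[1, "mi"] <- 2L
  expect_equal(linear_predictor(p, st, eq), 0.4)
  h_prior <- annual_hazard(p, st, eq)
  # hazard ratio between phases is exactly exp(beta_this - beta_prior)
  expect_equal(h_this / h_prior, exp(0.9 - 0.4), tolerance = 1e-12)
})

test_that("HbA1c term applies only without diagnosed diabetes", {
  eq <- risk_equation("mi", "no_cvd", log(0.01),
                      coefficients = c(hba1c_nondiab = 0.02))
  p <- reference_profile(hba1c = 46)  # 10 above centring
  st <- new_sim_state(p)
  expect_equal(linear_predictor(p, st, eq), 0.2)
  # incident diabetes switches the term off
  st$flags[1, "diabetes"] <- 1L
  st$diabetes_duration[1] <- 0
  expect_equal(linear_predictor(p, st, eq), 0)
  pd <- reference_profile(hba1c = 46, diabetes = "type2", diabetes_years = 2)
  expect_equal(linear_predictor(pd, new_sim_state(pd), eq), 0)
})

test_that("unresolvable covariate names raise a configuration error", {
  expect_error(risk_equation("mi", "no_cvd", log(0.01),
                             coefficients = c(nope = 1)),
               "nope", class = "cvd_config_error")
  expect_error(resolve_covariates("nope", reference_profile()),
               "nope", class = "cvd_config_error")
})

test_that("annual hazard has the Gompertz closed forms", {
  p <- reference_profile(age = 60)
  st <- new_sim_state(p)
  eq <- risk_equation("mi", "no_cvd", log(0.01), age_slope = 0)
  expect_equal(annual_hazard(p, st, eq), 0.01, tolerance = 1e-12)
  eq8 <- risk_equation("mi", "no_cvd", log(0.01), age_slope = 0.08)
  st70 <- st; st70$current_age <- 70
  st60 <- st; st60$current_age <- 60
  expect_equal(annual_hazard(p, st70, eq8) / annual_hazard(p, st60, eq8),
               exp(0.8), tolerance = 1e-12)
  # calibration shifts are additive on the log baseline
  eqs <- risk_equation("mi", "no_cvd", log(0.01), age_slope = 0.08,
                       intercept_shift = log(2), slope_shift = 0.01)
  expect_equal(annual_hazard(p, st70, eqs),
               0.01 * 2 * exp(0.09 * 10), tolerance = 1e-12)
})

test_that("hazard is proportional in exp(linear predictor) and monotone in age", {
  cs <- synthetic_true_model()
  co <- generate_cohort(30, seed = 5)
  st <- new_sim_state(co)
  eq <- cs$equations[["nonvascular_death.no_cvd"]]
  h0 <- annual_hazard(co, st, eq, cs$centring)
  # multiplying exp(lp) by c multiplies the hazard by exactly c
  eq2 <- eq
  eq2$coefficients[["male"]] <- eq$coefficients[["male"]] + log(3)
  h2 <- annual_hazard(co, st, eq2, cs$centring)
  male <- co$sex == "male"
  expect_equal(h2[male] / h0[male], rep(3, sum(male)), tolerance = 1e-12)
  expect_equal(h2[!male], h0[!male], tolerance = 1e-12)
  # nondecreasing in age for nonnegative slopes, across random profiles
  for (da in c(1, 5, 20)) {
    sta <- st; sta$current_age <- st$current_age + da
    expect_true(all(annual_hazard(co, sta, eq, cs$centring) >= h0))
  }
})

test_that("annual event probability is the exact exponential discretization", {
  expect_identical(annual_event_probability(0), 0)
  expect_equal(annual_event_probability(0.02), 1 - exp(-0.02))
  expect_error(annual_event_probability(-0.1), class = "cvd_domain_error")
  h <- c(1e-6, 1e-4, 0.003, 0.01)
  p <- annual_event_probability(h)
  expect_true(all(p > 0 & p < h))
  # Taylor bound |p - h| <= h^2/2 for small hazards
  expect_true(all(abs(p - h) <= h^2 / 2))
  expect_true(all(diff(annual_event_probability(seq(0, 5, 0.1))) > 0))
  expect_lte(annual_event_probability(1e9), 1)
})

test_that("ten-year MVE risk is zero without vascular hazards and matches the closed form", {
  p <- typical_profile()
  cs0 <- flat_model(hazards = c(cancer = 0.01, nonvascular_death = 1e-12))
  expect_equal(ten_year_mve_risk(p, cs0, reps = 50, seed = 1), 0)
  # constant total MVE hazard 0.0053/yr, no competing death
  cs1 <- flat_model(hazards = c(mi = 0.0020, stroke = 0.0015, crv = 0.0010,
                                vascular_death = 0.0008))
  risk <- ten_year_mve_risk(p, cs1, reps = 4000, seed = 2)
  want <- 100 * (1 - exp(-0.053))
  se <- 100 * sqrt(want / 100 * (1 - want / 100) / 4000)
  expect_lt(abs(risk - want), 2.5 * se)
  # the deterministic screening score agrees with the same closed form
  expect_equal(ten_year_risk_score(p, cs1), want, tolerance = 1e-9)
})

test_that("risk is monotone in the LDL effect under common random numbers", {
  p <- reference_profile(ldl = default_centring()$ldl + 1)
  risks <- vapply(c(0, 0.3, 0.6), function(b) {
    cs <- flat_model(hazards = c(mi = 0.004, vascular_death = 0.001),
                     coefs = list(mi = c(ldl = b)))
    ten_year_mve_risk(p, cs, reps = 300, seed = 7)
  }, 0)
  expect_true(all(diff(risks) >= 0))
})
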