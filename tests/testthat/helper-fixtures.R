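# Shared builders for tests: all fixtures are generated in code.

# a single fully specified reference-level profile (white never-smoking
# female, BMI 18.5-25, quintile 1, no histories, biomarkers at the centring
# constants so all centred covariates are zero)
reference_profile <- function(age = 60, ...) {
  ct <- default_centring()
  df <- data.frame(
    person_id = "ref1", age_entry = age, sex = "female", ethnicity = "white",
    smoking = "never", bmi_category = "18.5-25", ldl = ct$ldl, hdl = ct$hdl,
    hba1c = ct$hba1c, creatinine = ct$creatinine, sbp = ct$sbp, dbp = ct$dbp,
    treated_hypertension = 0L, diabetes = "none", diabetes_years = NA_real_,
    cancer_history = 0L, cvd_mi = 0L, cvd_stroke = 0L, cvd_crv = 0L,
    cvd_pad = 0L, cvd_other_chd = 0L, severe_mental_illness = 0L,
    physical_activity = "high", diet_unhealthy = 0L, townsend_quintile = 1L,
    statin_at_entry = 0L)
  ov <- list(...)
  df[names(ov)] <- ov
  validate_cohort(df)
}

# the worked-example style profile: 60-year-old white man, non-smoker,
# overweight, quintile 3, moderate activity, healthy diet, LDL 3.6, HDL 1.0,
# creatinine 82, BP 140/80, HbA1c 40, no treatments or histories
typical_profile <- function() {
  reference_profile(age = 60, sex = "male", bmi_category = "25-30",
                    ldl = 3.6, hdl = 1.0, creatinine = 82, sbp = 140,
                    dbp = 80, hba1c = 40, physical_activity = "moderate",
                    townsend_quintile = 3L)
}

# coefficient set in which every endpoint has a flat hazard given by
# `hazards` (named; unnamed endpoints get a negligible ~0 hazard) and an
# optional shared covariate map per endpoint; utility fixed at `utility`.
flat_model <- function(hazards = c(), coefs = list(), slopes = c(),
                       utility = 1, qol_coefs = numeric(0)) {
  req <- cvdmicrosim:::required_equations()
  eqs <- lapply(seq_len(nrow(req)), function(i) {
    e <- req$endpoint[i]
    h <- if (e %in% names(hazards)) hazards[[e]] else 1e-12
    risk_equation(e, req$population[i],
                  log_hazard_intercept = log(h),
                  age_slope = if (e %in% names(slopes)) slopes[[e]] else 0,
                  coefficients = if (!is.null(coefs[[e]])) coefs[[e]]
                                 else numeric(0))
  })
  coefficient_set(eqs, qol_model(utility, qol_coefs))
}

expect_no_error <- function(expr) expect_error(expr, NA)
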