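## ---------------------------------------------------------------------------
## Statin treatment policy: guideline eligibility, LDL-mediated hazard
## modification, and full-coverage vs real-world-uptake scenarios with
## common random numbers against a no-statin counterfactual.
## ---------------------------------------------------------------------------

#' Guideline statin eligibility rule
#'
#' Atorvastatin 20mg/day for individuals without CVD history but with a
#' 10-year CVD risk at or above the threshold, and/or type 1 diabetes, an
#' eGFR below the threshold, or albuminuria; atorvastatin 80mg/day for
#' individuals with CVD history, downgraded to 20mg when eGFR is below the
#' threshold.
#'
#' @param ten_year_risk_threshold percent (default 10).
#' @param egfr_threshold mL/min/1.73m^2 (default 60).
#' @return `statin_rule` list.
#' @export
statin_rule <- function(ten_year_risk_threshold = 10, egfr_threshold = 60) {
  stopifnot(ten_year_risk_threshold > 0, egfr_threshold > 0)
  structure(list(ten_year_risk_threshold = ten_year_risk_threshold,
                 egfr_threshold = egfr_threshold),
            class = "statin_rule")
}

#' Statin treatment effect parameters
#'
#' How a regimen modifies hazards: each regimen lowers LDL by a fraction of
#' its baseline value, and each affected vascular endpoint's hazard is
#' multiplied by `rate_ratio_per_mmol ^ (LDL reduction in mmol/L)`. All
#' numeric values are required configuration -- the package hard-codes no
#' effect sizes.
#'
#' @param ldl_reduction_fraction named fractions in `[0, 1)` per regimen
#'   (`atorva20`, `atorva80`).
#' @param rate_ratio_per_mmol named rate ratios in `(0, 1]` per affected
#'   endpoint, per 1 mmol/L of LDL lowering.
#' @param affected_endpoints subset of `mi, stroke, crv, vascular_death`
#'   (defaults to the names of `rate_ratio_per_mmol`).
#' @return `treatment_effect` list.
#' @export
treatment_effect <- function(ldl_reduction_fraction, rate_ratio_per_mmol,
                             affected_endpoints = names(rate_ratio_per_mmol)) {
  lf <- unlist(ldl_reduction_fraction)
  rr <- unlist(rate_ratio_per_mmol)
  if (!all(c("atorva20", "atorva80") %in% names(lf))) {
    cvd_error("cvd_config_error",
              "ldl_reduction_fraction must name atorva20 and atorva80")
  }
  if (any(lf < 0 | lf >= 1)) {
    cvd_error("cvd_config_error", "ldl_reduction_fraction must be in [0, 1)")
  }
  if (!length(rr) || is.null(names(rr))) {
    cvd_error("cvd_config_error", "rate_ratio_per_mmol must be a named map")
  }
  if (any(rr <= 0 | rr > 1)) {
    cvd_error("cvd_config_error", "rate ratios must be in (0, 1]")
  }
  bad <- setdiff(affected_endpoints, MVE_ENDPOINTS)
  if (length(bad)) {
    cvd_error("cvd_config_error",
              paste0("affected endpoints must be vascular: ",
                     paste(bad, collapse = ", ")))
  }
  structure(list(ldl_reduction_fraction = lf,
                 rate_ratio_per_mmol = rr[affected_endpoints],
                 affected_endpoints = affected_endpoints),
            class = "treatment_effect")
}

#' Assign a statin regimen under the eligibility rule
#'
#' Deterministic and pure: CVD history implies atorvastatin 80mg (20mg when
#' eGFR is below the rule threshold); otherwise 20mg when the 10-year risk
#' meets the threshold, or with type 1 diabetes, low eGFR, or albuminuria;
#' otherwise none. eGFR is taken from the profile when present and otherwise
#' derived from creatinine, age and sex ([egfr_ckdepi()]).
#'
#' @param cohort validated cohort.
#' @param risk 10-year CVD risk in percent (externally supplied score or
#'   [ten_year_risk_score()] / [ten_year_mve_risk()] output); required for
#'   primary-prevention rows.
#' @param rule a [statin_rule()].
#' @return character vector: `"atorva80"`, `"atorva20"` or `"none"`.
#' @export
assign_statin <- function(cohort, risk = cohort$ten_year_cvd_risk,
                          rule = statin_rule()) {
  n <- nrow(cohort)
  cvd <- has_cvd_history(cohort)
  if (is.null(risk)) risk <- rep(NA_real_, n)
  if (any(!cvd & is.na(risk))) {
    cvd_error("cvd_config_error",
              paste0("10-year risk missing for primary-prevention ",
                     "individual(s): supply a score source"))
  }
  egfr <- cohort_egfr(cohort)
  low_egfr <- egfr < rule$egfr_threshold
  albu <- if (is.null(cohort$albuminuria)) rep(0L, n) else
    ifelse(is.na(cohort$albuminuria), 0L, cohort$albuminuria)
  out <- rep("none", n)
  qualifies <- !cvd & (risk >= rule$ten_year_risk_threshold |
                         cohort$diabetes == "type1" | low_egfr | albu == 1L)
  out[qualifies] <- "atorva20"
  out[cvd] <- ifelse(low_egfr[cvd], "atorva20", "atorva80")
  out
}

#' Translate regimens into per-endpoint hazard multipliers
#'
#' For each treated person, the LDL reduction is
#' `ldl_reduction_fraction[regimen] * baseline LDL` (mmol/L) and each
#' affected endpoint's hazard is multiplied by
#' `rate_ratio_per_mmol ^ reduction`. Returns the log-multiplier matrix the
#' simulation consumes, with the achieved LDL and multipliers attached for
#' audit. A regimen of `"none"` is the identity.
#'
#' @param cohort validated cohort.
#' @param regimen character vector from [assign_statin()].
#' @param effect a [treatment_effect()].
#' @return `n x 7` matrix of log hazard multipliers; attributes `ldl_current`
#'   (post-treatment LDL) and `ldl_reduction`.
#' @export
apply_treatment <- function(cohort, regimen, effect) {
  n <- nrow(cohort)
  stopifnot(length(regimen) == n)
  bad <- setdiff(unique(regimen), c("none", names(effect$ldl_reduction_fraction)))
  if (length(bad)) {
    cvd_error("cvd_config_error",
              paste0("unknown regimen: ", paste(bad, collapse = ", ")))
  }
  frac <- ifelse(regimen == "none", 0,
                 effect$ldl_reduction_fraction[regimen])
  dldl <- frac * cohort$ldl
  log_mult <- matrix(0, n, length(ENDPOINTS),
                     dimnames = list(NULL, ENDPOINTS))
  for (e in effect$affected_endpoints) {
    log_mult[, e] <- dldl * log(effect$rate_ratio_per_mmol[[e]])
  }
  attr(log_mult, "ldl_reduction") <- dldl
  attr(log_mult, "ldl_current") <- cohort$ldl - dldl
  log_mult
}

#' Run a statin treatment scenario against a no-statin counterfactual
#'
#' Eligibility is assessed once at entry; a treated indicator is drawn once
#' per person per replicate with quintile-specific uptake (full coverage =
#' uptake 1 everywhere); treated and counterfactual arms are simulated with
#' common random numbers, so the contrast is low-variance and uptake 0 gives
#' exactly zero gain. Treatment, once assigned, is maintained lifelong.
#'
#' @param cohort validated cohort.
#' @param coefset `coefficient_set`.
#' @param rule a [statin_rule()].
#' @param effect a [treatment_effect()].
#' @param uptake named probabilities per deprivation quintile `"1"`..`"5"`,
#'   or a single probability applied everywhere.
#' @param config `sim_config`.
#' @param risk_source `"profile"` (use `ten_year_cvd_risk`, falling back to
#'   the internal deterministic score when absent) or `"internal"`.
#' @return list: `summary` (life years and QALYs gained per 1000 by sex x
#'   age band x quintile, with fraction eligible), `person` (per-person mean
#'   gains), `eligible`, `regimen`, `risk`.
#' @export
run_scenario <- function(cohort, coefset, rule, effect, uptake = 1,
                         config = sim_config(), risk_source = "profile") {
  n <- nrow(cohort)
  if (length(uptake) == 1 && is.null(names(uptake))) {
    uptake <- stats::setNames(rep(uptake, 5), 1:5)
  }
  miss <- setdiff(as.character(1:5), names(uptake))
  if (length(miss)) {
    cvd_error("cvd_config_error",
              paste0("uptake missing quintile(s): ",
                     paste(miss, collapse = ", ")))
  }
  if (any(uptake < 0 | uptake > 1)) {
    cvd_error("cvd_config_error", "uptake probabilities must be in [0, 1]")
  }
  risk <- if (identical(risk_source, "internal") ||
              is.null(cohort$ten_year_cvd_risk) ||
              anyNA(cohort$ten_year_cvd_risk)) {
    ten_year_risk_score(cohort, coefset)
  } else {
    cohort$ten_year_cvd_risk
  }
  regimen <- assign_statin(cohort, risk, rule)
  eligible <- regimen != "none"
  log_mult_full <- apply_treatment(cohort, regimen, effect)
  p_take <- unname(uptake[as.character(cohort$townsend_quintile)]) * eligible
  R <- config$replicates
  gain <- matrix(0, n, 4,
                 dimnames = list(NULL, c("ly", "qaly", "ly10", "ly20")))
  for (r in seq_len(R)) {
    set.seed(derive_seed(config$master_seed, 900001, r))
    treated <- stats::runif(n) < p_take
    lm_r <- log_mult_full
    lm_r[!treated, ] <- 0
    ctx0 <- build_sim_context(cohort, coefset, NULL)
    ctx1 <- build_sim_context(cohort, coefset, lm_r)
    a0 <- engine_run(ctx0, config, replicate = r)
    a1 <- engine_run(ctx1, config, replicate = r)
    gain <- gain + cbind(ly = a1$ly - a0$ly, qaly = a1$qaly - a0$qaly,
                         ly10 = a1$ly10 - a0$ly10, ly20 = a1$ly20 - a0$ly20)
  }
  gain <- gain / R
  person <- data.frame(person_id = cohort$person_id,
                       eligible = eligible, regimen = regimen,
                       ly_gain = gain[, "ly"], qaly_gain = gain[, "qaly"],
                       ly10_gain = gain[, "ly10"], ly20_gain = gain[, "ly20"])
  cat_df <- data.frame(sex = cohort$sex,
                       age_band = age_band(cohort$age_entry),
                       quintile = cohort$townsend_quintile)
  key <- interaction(cat_df, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(n), key), function(ix) {
    data.frame(cat_df[ix[1], ], n = length(ix),
               fraction_eligible = mean(eligible[ix]),
               ly_gained_per_1000 = 1000 * mean(gain[ix, "ly"]),
               qalys_gained_per_1000 = 1000 * mean(gain[ix, "qaly"]))
  }))
  rownames(agg) <- NULL
  list(summary = agg, person = person, eligible = eligible,
       regimen = regimen, risk = risk,
       egfr_source = if (is.null(cohort$egfr) || anyNA(cohort$egfr))
         "derived (CKD-EPI 2021 creatinine)" else "profile")
}
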