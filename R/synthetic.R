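## ---------------------------------------------------------------------------
## Synthetic data: cohorts with the covariate structure of a contemporary UK
## middle-aged population cohort, follow-up data sampled from known true
## hazards by an independent continuous-time competing-risks implementation
## (the engine's oracle), utility surveys, and reference weight tables.
## ---------------------------------------------------------------------------

#' Cohort generator configuration
#'
#' Marginal distributions default to the primary-prevention column of the
#' source cohort's baseline table: 44% male, age mean 56 SD 8.1 truncated to
#' 40-70, LDL mean 3.6 SD 0.82 mmol/L, deprivation quintile shares
#' 37/20/16/14/13%, and so on. Any marginal can be overridden; an optional
#' Gaussian copula induces dependence between the continuous biomarkers.
#'
#' @param ... overrides of the default fields.
#' @return `cohort_config` list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    p_male = 0.44,
    age = c(mean = 56, sd = 8.1, lo = 40, hi = 70),
    ethnicity = c(white = 0.948, black = 0.016, south_asian = 0.016,
                  other = 0.020),
    smoking = c(never = 0.56, ex = 0.34, current = 0.10),
    bmi = c("<18.5" = 0.005, "18.5-25" = 0.34, "25-30" = 0.43,
            "30-35" = 0.17, "35-40" = 0.046, "40+" = 0.019),
    ldl = c(mean = 3.6, sd = 0.82, lo = 0.5, hi = 10),
    hdl = c(mean = 1.5, sd = 0.37, lo = 0.4, hi = 5),
    hba1c = c(mean = 35.8, sd = 6.2, lo = 15, hi = 120),
    creatinine = c(mean = 71, sd = 15, lo = 20, hi = 400),
    sbp = c(mean = 138, sd = 19, lo = 70, hi = 250),
    dbp = c(mean = 82, sd = 10, lo = 40, hi = 150),
    p_treated_htn = 0.16,
    diabetes = c(none = 0.951, type1 = 0.006, type2 = 0.043),
    diabetes_years_max = 15,
    p_cancer = 0.074,
    p_cvd = 0,
    cvd_mix = c(mi = 0.36, other_chd = 0.51, pad = 0.12, stroke = 0.09,
                crv = 0.10),
    p_smi = 0.08,
    physical_activity = c(high = 0.33, moderate = 0.33, low = 0.15,
                          missing = 0.19),
    p_diet_unhealthy = 0.36,
    townsend = c(0.37, 0.20, 0.16, 0.14, 0.13),
    p_statin = 0,
    copula_corr = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    cvd_error("cvd_config_error",
              paste0("unknown cohort_config field(s): ",
                     paste(unknown, collapse = ", ")))
  }
  cfg[names(ov)] <- ov
  for (p in c("ethnicity", "smoking", "bmi", "diabetes", "physical_activity",
              "townsend")) {
    v <- cfg[[p]]
    if (any(v < 0) || sum(v) <= 0) {
      cvd_error("cvd_config_error", paste0("invalid probabilities for ", p))
    }
    cfg[[p]] <- v / sum(v)
  }
  structure(cfg, class = "cohort_config")
}

## truncated-normal quantile transform
qtnorm <- function(u, spec) {
  plo <- stats::pnorm(spec[["lo"]], spec[["mean"]], spec[["sd"]])
  phi <- stats::pnorm(spec[["hi"]], spec[["mean"]], spec[["sd"]])
  stats::qnorm(plo + u * (phi - plo), spec[["mean"]], spec[["sd"]])
}

rcat <- function(n, probs) {
  names(probs)[1 + findInterval(stats::runif(n), cumsum(probs),
                                rightmost.closed = TRUE)]
}

#' Generate a synthetic cohort
#'
#' Draws `n` individual profiles from the configured marginals (truncated
#' normals for continuous biomarkers, categorical draws elsewhere), with an
#' optional Gaussian copula across the continuous variables. Deterministic
#' per seed.
#'
#' @param n cohort size (>= 1).
#' @param seed integer seed.
#' @param config a [cohort_config()].
#' @return validated `cvd_cohort` of `n` rows.
#' @export
generate_cohort <- function(n, seed = 1, config = cohort_config()) {
  stopifnot(n >= 1)
  set.seed(derive_seed(seed, 101))
  cont <- c("age", "ldl", "hdl", "hba1c", "creatinine", "sbp", "dbp")
  if (!is.null(config$copula_corr)) {
    R <- config$copula_corr
    if (!is.matrix(R) || !all(cont %in% rownames(R))) {
      cvd_error("cvd_config_error",
                "copula_corr must be a correlation matrix over the continuous variables")
    }
    L <- tryCatch(chol(R[cont, cont]), error = function(e)
      cvd_error("cvd_config_error", "copula_corr is not positive definite"))
    Z <- matrix(stats::rnorm(n * length(cont)), n) %*% L
    U <- stats::pnorm(Z); colnames(U) <- cont
  } else {
    U <- matrix(stats::runif(n * length(cont)), n,
                dimnames = list(NULL, cont))
  }
  draw <- function(v) qtnorm(U[, v], config[[v]])
  diabetes <- rcat(n, config$diabetes)
  has_cvd <- stats::runif(n) < config$p_cvd
  cvd_flags <- matrix(0L, n, 5,
                      dimnames = list(NULL, c("mi", "other_chd", "pad",
                                              "stroke", "crv")))
  if (any(has_cvd)) {
    for (k in colnames(cvd_flags)) {
      cvd_flags[has_cvd, k] <-
        as.integer(stats::runif(sum(has_cvd)) < config$cvd_mix[[k]])
    }
    ## guarantee at least one history component
    none <- has_cvd & rowSums(cvd_flags) == 0
    cvd_flags[none, "other_chd"] <- 1L
  }
  df <- data.frame(
    person_id = sprintf("p%07d", seq_len(n)),
    age_entry = round(draw("age"), 1),
    sex = ifelse(stats::runif(n) < config$p_male, "male", "female"),
    ethnicity = rcat(n, config$ethnicity),
    smoking = rcat(n, config$smoking),
    bmi_category = rcat(n, config$bmi),
    ldl = round(draw("ldl"), 2),
    hdl = round(draw("hdl"), 2),
    hba1c = round(draw("hba1c"), 1),
    creatinine = round(draw("creatinine"), 1),
    sbp = round(draw("sbp"), 1),
    dbp = round(draw("dbp"), 1),
    treated_hypertension = as.integer(stats::runif(n) < config$p_treated_htn),
    diabetes = diabetes,
    diabetes_years = ifelse(diabetes == "none", NA_real_,
                            round(stats::runif(n, 0, config$diabetes_years_max), 1)),
    cancer_history = as.integer(stats::runif(n) < config$p_cancer),
    cvd_mi = cvd_flags[, "mi"],
    cvd_stroke = cvd_flags[, "stroke"],
    cvd_crv = cvd_flags[, "crv"],
    cvd_pad = cvd_flags[, "pad"],
    cvd_other_chd = cvd_flags[, "other_chd"],
    severe_mental_illness = as.integer(stats::runif(n) < config$p_smi),
    physical_activity = rcat(n, config$physical_activity),
    diet_unhealthy = as.integer(stats::runif(n) < config$p_diet_unhealthy),
    townsend_quintile = as.integer(rcat(n, stats::setNames(config$townsend, 1:5))),
    statin_at_entry = as.integer(stats::runif(n) < config$p_statin))
  validate_cohort(df)
}

## ---------------------------------------------------------------------------
## Continuous-time competing-risks oracle. Within each year, cause-specific
## exponential event times are drawn from the current hazards; the earliest
## time inside the year fires, the state updates mid-year (so remaining
## endpoints race at updated hazards for the rest of the year, using the
## memorylessness of the exponential), and survivors roll to the next year.
## This shares NO event-sampling code with the annual-cycle engine, making
## the engine/oracle equivalence test meaningful.
## ---------------------------------------------------------------------------

oracle_hazard_matrix <- function(cohort, state, coefset, baseline_hist, cvd) {
  n <- nrow(cohort)
  H <- matrix(0, n, length(ENDPOINTS), dimnames = list(NULL, ENDPOINTS))
  for (e in ENDPOINTS) {
    if (e %in% POOLED_ENDPOINTS) {
      H[, e] <- annual_hazard(cohort, state, get_equation(coefset, e, "pooled"),
                              coefset$centring)
    } else {
      if (any(!cvd)) {
        h <- annual_hazard(cohort, state, get_equation(coefset, e, "no_cvd"),
                           coefset$centring)
        H[!cvd, e] <- h[!cvd]
      }
      if (any(cvd)) {
        h <- annual_hazard(cohort, state, get_equation(coefset, e, "cvd"),
                           coefset$centring)
        H[cvd, e] <- h[cvd]
      }
    }
  }
  ## not at risk: first occurrences only
  for (e in EVENT_ENDPOINTS) {
    H[baseline_hist[, e] | state$flags[, e] > 0L, e] <- 0
  }
  H
}

#' Generate follow-up data from known true equations (continuous-time oracle)
#'
#' Samples each person's event history in continuous time under the supplied
#' coefficient set: within each year, cause-specific exponential times from
#' the current hazards compete; the first time inside the year fires and the
#' state updates immediately (event-year effects apply for the remainder of
#' that year, then roll to prior-years). Follow-up ends at death, `max_years`
#' or age 110. Independent of the simulation engine's event-sampling code.
#'
#' @param cohort validated cohort.
#' @param coefset true `coefficient_set`.
#' @param max_years administrative censoring horizon.
#' @param seed integer seed.
#' @return a [followup_data()] object.
#' @export
generate_followup <- function(cohort, coefset, max_years, seed = 1) {
  n <- nrow(cohort)
  set.seed(derive_seed(seed, 202))
  state <- new_sim_state(cohort)
  cvd <- has_cvd_history(cohort)
  baseline_hist <- cbind(
    mi = cohort$cvd_mi == 1, stroke = cohort$cvd_stroke == 1,
    crv = cohort$cvd_crv == 1, cancer = cohort$cancer_history == 1,
    diabetes = cohort$diabetes != "none")
  ev_person <- ev_endpoint <- ev_time <- list(); k <- 0L
  end_time <- rep(NA_real_, n)
  year <- 0L
  while (any(state$alive) && year < max_years) {
    active <- state$alive & state$current_age < AGE_CAP
    if (!any(active)) break
    t_in_year <- numeric(n)
    pending <- active
    H <- NULL
    while (any(pending)) {
      if (is.null(H)) {
        H <- oracle_hazard_matrix(cohort, state, coefset, baseline_hist, cvd)
      } else {
        ## only persons who fired in the previous round have changed state
        rows <- which(pending)
        sub <- cohort[rows, , drop = FALSE]; class(sub) <- class(cohort)
        H[rows, ] <- oracle_hazard_matrix(sub, state_subset(state, rows),
                                          coefset,
                                          baseline_hist[rows, , drop = FALSE],
                                          cvd[rows])
      }
      E <- matrix(stats::rexp(n * length(ENDPOINTS)), n) / H  # 0-hazard -> Inf
      tmin <- E[, 1]
      for (j in 2:ncol(E)) tmin <- pmin(tmin, E[, j])
      fires <- pending & (t_in_year + tmin < 1)
      pending <- fires
      if (!any(fires)) break
      widx <- which(fires)
      wcol <- max.col(-E[widx, , drop = FALSE], ties.method = "first")
      t_abs <- year + t_in_year[widx] + tmin[widx]
      t_in_year[widx] <- t_in_year[widx] + tmin[widx]
      for (m in seq_along(widx)) {
        i <- widx[m]; e <- ENDPOINTS[wcol[m]]
        k <- k + 1L
        ev_person[[k]] <- cohort$person_id[i]
        ev_endpoint[[k]] <- e
        ev_time[[k]] <- t_abs[m]
        if (e %in% EVENT_ENDPOINTS) {
          state$flags[i, e] <- 1L
          state$years_since[i, e] <- 0
          if (e == "diabetes") {
            state$diabetes_duration[i] <- 0
            state$diabetes_type[i] <- "type2"
          }
        } else {
          state$alive[i] <- FALSE
          state$cause_of_death[i] <-
            if (e == "vascular_death") "vascular" else "nonvascular"
          end_time[i] <- t_abs[m]
          pending[i] <- FALSE
        }
      }
    }
    ## year-end roll for survivors
    surv <- active & state$alive
    state$current_age[surv] <- state$current_age[surv] + 1
    roll <- state$flags == 1L & matrix(surv, n, 5)
    state$flags[roll] <- 2L
    prior <- state$flags == 2L & matrix(surv, n, 5)
    state$years_since[prior] <- state$years_since[prior] + 1
    hd <- surv & !is.na(state$diabetes_duration)
    state$diabetes_duration[hd] <- state$diabetes_duration[hd] + 1
    ## persons reaching the age cap are censored at the year boundary
    capped <- surv & state$current_age >= AGE_CAP
    end_time[capped] <- year + 1
    state$alive[capped] <- FALSE
    state$cause_of_death[capped] <- "none"
    year <- year + 1L
  }
  end_time[is.na(end_time)] <- pmin(max_years,
                                    ceiling(AGE_CAP - cohort$age_entry))[is.na(end_time)]
  events <- if (k) data.frame(person_id = unlist(ev_person),
                              endpoint = unlist(ev_endpoint),
                              time = unlist(ev_time)) else
    data.frame(person_id = character(0), endpoint = character(0),
               time = numeric(0))
  fu <- followup_data(cohort, events, end_time)
  fu$final_state <- state
  fu
}

#' Generate a synthetic utility survey
#'
#' Survey-style records standing in for pooled health-survey data: covariates
#' from [generate_cohort()] plus randomly assigned event-history phases,
#' utility equal to the true model's linear prediction plus Gaussian noise,
#' clamped to `[-0.594, 1]`.
#'
#' @param n records.
#' @param true_qol the generating [qol_model()].
#' @param noise_sd Gaussian noise SD on the utility scale.
#' @param seed integer seed.
#' @param config cohort configuration for the covariates.
#' @return data frame with column `utility` plus one column per covariate of
#'   `true_qol`; attribute `clamped_fraction` records the share of records
#'   clamped at a bound.
#' @export
generate_utility_survey <- function(n, true_qol, noise_sd = 0.1, seed = 1,
                                    config = cohort_config()) {
  stopifnot(n >= 1)
  cohort <- generate_cohort(n, seed = derive_seed(seed, 301), config = config)
  set.seed(derive_seed(seed, 302))
  state <- new_sim_state(cohort)
  ## random incident event-history phases
  phase <- function(p_this, p_prior) {
    u <- stats::runif(n)
    ifelse(u < p_this, 1L, ifelse(u < p_this + p_prior, 2L, 0L))
  }
  state$flags[, "mi"] <- phase(0.01, 0.05)
  state$flags[, "stroke"] <- phase(0.01, 0.04)
  state$flags[, "cancer"] <- phase(0.005, 0.03)
  ys <- pmax(0, round(stats::runif(n, 0, 8)))
  for (e in c("mi", "stroke", "cancer")) {
    state$years_since[state$flags[, e] == 1L, e] <- 0
    state$years_since[state$flags[, e] == 2L, e] <- ys[state$flags[, e] == 2L]
  }
  nm <- names(true_qol$coefficients)
  X <- resolve_covariates(nm, cohort, state, default_centring())
  mu <- true_qol$intercept + drop(X %*% true_qol$coefficients)
  y_raw <- mu + stats::rnorm(n, 0, noise_sd)
  y <- clamp_utility(y_raw)
  out <- data.frame(utility = y)
  out <- cbind(out, as.data.frame(X))
  attr(out, "clamped_fraction") <- mean(y != y_raw)
  out
}

#' Synthetic reference-population weight table
#'
#' A deterministic stand-in for a national mid-2020 population distribution
#' by sex, 5-year age band (40-44 ... 65-69, 70+) and deprivation quintile:
#' quintiles are population fifths by construction; age-band shares decline
#' slowly with age; sexes split 49/51.
#'
#' @return a [reference_population()].
#' @export
generate_reference_weights <- function() {
  bands <- c("40-44", "45-49", "50-54", "55-59", "60-64", "65-69", "70+")
  band_share <- c(0.155, 0.155, 0.15, 0.145, 0.135, 0.125, 0.135)
  grid <- expand.grid(sex = SEX_LEVELS, age_band = bands, quintile = 1:5,
                      stringsAsFactors = FALSE)
  sex_share <- c(male = 0.49, female = 0.51)
  grid$weight <- sex_share[grid$sex] *
    band_share[match(grid$age_band, bands)] * 0.2
  reference_population(grid)
}

#' The synthetic true model used as a test fixture
#'
#' A complete coefficient set with modest Gompertz baselines (age slope
#' 0.09-0.10 per year on the death endpoints), event-history hazard ratios
#' largest in the year of event, a protective revascularisation effect on
#' vascular death, a deprivation log hazard ratio of log(1.15) per quintile
#' step on stroke, incident diabetes and both deaths, an HbA1c effect
#' restricted to those without diagnosed diabetes, and the utility decrement
#' structure (MI 0.10 year-of-event / 0.07 subsequent; stroke 0.09 / 0.13;
#' diabetes 0.04 first decade / 0.08 after; cancer 0.03). These values are
#' synthetic: they mirror the qualitative structure of published equations
#' without claiming any fitted magnitudes.
#'
#' @return a `coefficient_set` (identical to the packaged
#'   `synthetic_coefficients.json`).
#' @export
synthetic_true_model <- function() {
  dep <- log(1.15)
  eq <- function(...) risk_equation(...)
  equations <- list(
    ## -- primary prevention --------------------------------------------------
    eq("mi", "no_cvd", log(0.0016), 0.060, c(
      male = 0.45, smoke_current = 0.55, smoke_ex = 0.15,
      treated_hypertension = 0.30, ldl = 0.25, hdl = -0.40, sbp = 0.010,
      diabetes_lt10 = 0.50, diabetes_ge10 = 0.75, hba1c_nondiab = 0.015,
      bmi_30_35 = 0.15, bmi_35_40 = 0.25, bmi_40plus = 0.35,
      pa_low = 0.15, pa_missing = 0.05, diet_unhealthy = 0.10)),
    eq("stroke", "no_cvd", log(0.0009), 0.075, c(
      male = 0.20, smoke_current = 0.50, treated_hypertension = 0.35,
      sbp = 0.014, mi_this_year = 1.10, mi_prior_years = 0.45,
      diabetes_lt10 = 0.40, diabetes_ge10 = 0.65, hba1c_nondiab = 0.012,
      townsend = dep, pa_low = 0.12, diet_unhealthy = 0.08)),
    eq("crv", "no_cvd", log(0.0012), 0.045, c(
      male = 0.50, smoke_current = 0.35, ldl = 0.28, hdl = -0.35,
      treated_hypertension = 0.22, mi_this_year = 1.30, mi_prior_years = 0.60,
      diabetes_lt10 = 0.35, diabetes_ge10 = 0.55, hba1c_nondiab = 0.010)),
    eq("vascular_death", "no_cvd", log(0.0004), 0.100, c(
      male = 0.45, smoke_current = 0.70, treated_hypertension = 0.30,
      sbp = 0.012, mi_this_year = 1.90, mi_prior_years = 0.75,
      stroke_this_year = 1.70, stroke_prior_years = 0.80, crv_any = -0.25,
      diabetes_lt10 = 0.55, diabetes_ge10 = 0.85, hba1c_nondiab = 0.014,
      townsend = dep, pa_low = 0.20, diet_unhealthy = 0.12,
      severe_mental_illness = 0.25)),
    eq("nonvascular_death", "no_cvd", log(0.0045), 0.092, c(
      male = 0.30, smoke_current = 0.80, smoke_ex = 0.20, cancer_any = 0.90,
      townsend = dep, pa_low = 0.25, pa_missing = 0.10,
      severe_mental_illness = 0.35, diabetes_lt10 = 0.25,
      diabetes_ge10 = 0.45, bmi_lt18_5 = 0.50)),
    ## -- secondary prevention ------------------------------------------------
    eq("mi", "cvd", log(0.0080), 0.050, c(
      male = 0.35, smoke_current = 0.45, ldl = 0.22, hdl = -0.30,
      treated_hypertension = 0.25, hist_mi = 0.30, hist_other_chd = 0.20,
      diabetes_lt10 = 0.45, diabetes_ge10 = 0.65, hba1c_nondiab = 0.012)),
    eq("stroke", "cvd", log(0.0050), 0.070, c(
      male = 0.15, smoke_current = 0.45, treated_hypertension = 0.30,
      sbp = 0.012, mi_this_year = 0.90, mi_prior_years = 0.40,
      hist_stroke = 0.50, diabetes_lt10 = 0.35, diabetes_ge10 = 0.60,
      hba1c_nondiab = 0.010, townsend = dep)),
    eq("crv", "cvd", log(0.0100), 0.030, c(
      male = 0.40, ldl = 0.20, hdl = -0.25, mi_this_year = 1.10,
      mi_prior_years = 0.50, hist_mi = 0.35, diabetes_lt10 = 0.30,
      diabetes_ge10 = 0.50)),
    eq("vascular_death", "cvd", log(0.0060), 0.095, c(
      male = 0.40, smoke_current = 0.60, treated_hypertension = 0.25,
      sbp = 0.010, mi_this_year = 1.60, mi_prior_years = 0.60,
      stroke_this_year = 1.50, stroke_prior_years = 0.70, crv_any = -0.20,
      hist_mi = 0.25, hist_stroke = 0.30, hist_pad = 0.30,
      diabetes_lt10 = 0.50, diabetes_ge10 = 0.80, hba1c_nondiab = 0.012,
      townsend = dep, severe_mental_illness = 0.25)),
    eq("nonvascular_death", "cvd", log(0.0055), 0.090, c(
      male = 0.30, smoke_current = 0.75, smoke_ex = 0.20, cancer_any = 0.90,
      townsend = dep, pa_low = 0.25, severe_mental_illness = 0.35,
      diabetes_lt10 = 0.25, diabetes_ge10 = 0.45)),
    ## -- pooled --------------------------------------------------------------
    eq("cancer", "pooled", log(0.0060), 0.055, c(
      male = 0.15, smoke_current = 0.50, smoke_ex = 0.15, bmi_30_35 = 0.10,
      bmi_35_40 = 0.18, bmi_40plus = 0.25, diet_unhealthy = 0.08)),
    eq("diabetes", "pooled", log(0.0042), 0.020, c(
      male = 0.20, bmi_25_30 = 0.55, bmi_30_35 = 1.10, bmi_35_40 = 1.50,
      bmi_40plus = 1.90, hba1c_nondiab = 0.090, townsend = dep,
      pa_low = 0.20, smoke_current = 0.20)))
  qol <- qol_model(0.88, c(
    age_current = -0.0035, male = 0.015,
    mi_year_of_event = -0.10, mi_subsequent = -0.07,
    stroke_year_of_event = -0.09, stroke_subsequent = -0.13,
    diabetes_first_10y = -0.04, diabetes_after_10y = -0.08,
    cancer_any = -0.03, smoke_current = -0.02, pa_low = -0.04,
    bmi_40plus = -0.05, townsend = -0.008, severe_mental_illness = -0.08))
  coefficient_set(equations, qol)
}
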