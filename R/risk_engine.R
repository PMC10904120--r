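## ---------------------------------------------------------------------------
## Risk engine: a person's profile and current dynamic state -> per-endpoint
## annual hazards and event probabilities under a Gompertz proportional-hazards
## model on current age.
## ---------------------------------------------------------------------------

#' Initialize simulation state from a cohort
#'
#' The dynamic state carries everything that is updated annually: current age,
#' vital status and cause of death, first-occurrence event flags
#' (0 = never, 1 = this year, 2 = prior years), years since each incident
#' event, diabetes duration (entry duration for prevalent diabetes), statin
#' status and current LDL. Flags are monotone: the model simulates first
#' occurrences only.
#'
#' @param cohort validated cohort (`n` persons).
#' @return object of class `sim_state` holding parallel vectors/matrices of
#'   length/nrow `n`.
#' @export
new_sim_state <- function(cohort) {
  n <- nrow(cohort)
  flags <- matrix(0L, n, length(EVENT_ENDPOINTS),
                  dimnames = list(NULL, EVENT_ENDPOINTS))
  years_since <- matrix(NA_real_, n, length(EVENT_ENDPOINTS),
                        dimnames = list(NULL, EVENT_ENDPOINTS))
  structure(list(
    n = n,
    current_age = cohort$age_entry,
    alive = rep(TRUE, n),
    cause_of_death = rep("none", n),
    flags = flags,
    years_since = years_since,
    diabetes_duration = ifelse(cohort$diabetes != "none",
                               cohort$diabetes_years, NA_real_),
    diabetes_type = cohort$diabetes,
    on_statin = cohort$statin_at_entry == 1,
    ldl_current = cohort$ldl
  ), class = "sim_state")
}

check_state <- function(state) {
  bad <- state$alive & state$current_age > AGE_CAP
  if (any(bad)) {
    cvd_error("cvd_state_error",
              sprintf("alive beyond the age cap of %d", AGE_CAP))
  }
  invisible(state)
}

#' Linear predictor of a risk equation
#'
#' Sum over the equation's coefficients of covariate value times log hazard
#' ratio, resolved through the shared registry. Event-history terms select the
#' year-of-event coefficient in the event year and the subsequent-years
#' coefficient afterwards; the HbA1c term contributes only for individuals
#' without diagnosed diabetes. A reference-level profile with empty history
#' has linear predictor 0.
#'
#' @param cohort validated cohort (may be a single row).
#' @param state `sim_state` aligned with `cohort`.
#' @param eq a [risk_equation()].
#' @param centring centring constants (from the coefficient set).
#' @return numeric vector of log hazard-ratio sums.
#' @export
linear_predictor <- function(cohort, state, eq,
                             centring = default_centring()) {
  if (!length(eq$coefficients)) return(numeric(nrow(cohort)))
  X <- resolve_covariates(names(eq$coefficients), cohort, state, centring)
  drop(X %*% eq$coefficients)
}

#' Annual hazard under a risk equation
#'
#' `exp(b0 + intercept_shift + (slope + slope_shift) * (age - age_centre) +
#' linear_predictor)`: a Gompertz baseline on current age times the
#' proportional-hazards covariate term, with additive calibration shifts on
#' the log baseline.
#'
#' @inheritParams linear_predictor
#' @return nonnegative hazards (events/year).
#' @export
annual_hazard <- function(cohort, state, eq, centring = default_centring()) {
  lp <- linear_predictor(cohort, state, eq, centring)
  h <- exp(eq$baseline$log_hazard_intercept + eq$calibration$intercept_shift +
             (eq$baseline$age_slope + eq$calibration$slope_shift) *
             (state$current_age - centring$age) + lp)
  if (any(!is.finite(h) & state$alive)) {
    cvd_error("cvd_numeric_error",
              "non-finite hazard (check the coefficient file)")
  }
  h
}

#' Annual event probability from a constant within-cycle hazard
#'
#' Discretization of the continuous-time hazard to the model's annual cycle:
#' `p = 1 - exp(-h)`, the probability that an event with constant hazard `h`
#' occurs within one year. Strictly increasing in `h`, 0 iff `h = 0`, and
#' bounded below 1 for finite `h`.
#'
#' @param h nonnegative hazard (events/year).
#' @return probability in `[0, 1)`.
#' @export
annual_event_probability <- function(h) {
  if (any(h < 0, na.rm = TRUE)) {
    cvd_error("cvd_domain_error", "hazard must be nonnegative")
  }
  -expm1(-h)
}

## ---------------------------------------------------------------------------
## Simulation context: per-equation resolution of population membership and
## precomputed static linear predictors, so each cycle only recomputes the
## dynamic (state-dependent) covariates.
## ---------------------------------------------------------------------------

build_sim_context <- function(cohort, coefset, log_mult = NULL) {
  n <- nrow(cohort)
  cvd <- has_cvd_history(cohort)
  reg <- covariate_registry()
  if (is.null(log_mult)) {
    log_mult <- matrix(0, n, length(ENDPOINTS),
                       dimnames = list(NULL, ENDPOINTS))
  }
  ct <- coefset$centring
  groups <- list()
  for (e in ENDPOINTS) {
    if (e %in% POOLED_ENDPOINTS) {
      pops <- list(pooled = rep(TRUE, n))
    } else {
      pops <- list(no_cvd = !cvd, cvd = cvd)
    }
    gl <- list()
    for (pop in names(pops)) {
      members <- pops[[pop]]
      if (!any(members)) next
      eq <- get_equation(coefset, e, pop)
      nm <- names(eq$coefficients)
      is_dyn <- vapply(reg[nm], `[[`, TRUE, "dynamic")
      static_nm <- nm[!is_dyn]
      dyn_nm <- nm[is_dyn]
      static_lp <- numeric(n)
      if (length(static_nm)) {
        X <- resolve_covariates(static_nm, cohort, NULL, ct)
        static_lp <- drop(X %*% eq$coefficients[static_nm])
      }
      gl[[pop]] <- list(members = members, eq = eq,
                        static_lp = static_lp, dyn = dyn_nm)
    }
    groups[[e]] <- gl
  }
  ## utility model split the same way
  qnm <- names(coefset$qol$coefficients)
  q_dyn <- if (length(qnm)) vapply(reg[qnm], `[[`, TRUE, "dynamic") else logical(0)
  q_static_lp <- numeric(n)
  if (any(!q_dyn)) {
    X <- resolve_covariates(qnm[!q_dyn], cohort, NULL, ct)
    q_static_lp <- drop(X %*% coefset$qol$coefficients[qnm[!q_dyn]])
  }
  ## endpoints never simulated because already in baseline history
  baseline_hist <- cbind(
    mi = cohort$cvd_mi == 1, stroke = cohort$cvd_stroke == 1,
    crv = cohort$cvd_crv == 1, cancer = cohort$cancer_history == 1,
    diabetes = cohort$diabetes != "none")
  list(cohort = cohort, coefset = coefset, centring = ct, groups = groups,
       log_mult = log_mult, baseline_hist = baseline_hist,
       qol_static_lp = q_static_lp, qol_dyn = qnm[q_dyn])
}

## row subset of a simulation state (used for targeted hazard recomputation)
state_subset <- function(state, idx) {
  structure(list(
    n = length(idx),
    current_age = state$current_age[idx],
    alive = state$alive[idx],
    cause_of_death = state$cause_of_death[idx],
    flags = state$flags[idx, , drop = FALSE],
    years_since = state$years_since[idx, , drop = FALSE],
    diabetes_duration = state$diabetes_duration[idx],
    diabetes_type = state$diabetes_type[idx],
    on_statin = state$on_statin[idx],
    ldl_current = state$ldl_current[idx]
  ), class = "sim_state")
}

## hazards for one endpoint over a logical selection of persons (full-n vector
## returned, zero outside the selection); with `rows` (integer indices) only
## those rows are computed, on subsetted data
ctx_hazard <- function(ctx, state, endpoint, sel, rows = NULL) {
  ei <- match(endpoint, ENDPOINTS)
  if (!is.null(rows)) {
    sub_cohort <- ctx$cohort[rows, , drop = FALSE]
    class(sub_cohort) <- class(ctx$cohort)
    sub_state <- state_subset(state, rows)
    hs <- numeric(length(rows))
    for (g in ctx$groups[[endpoint]]) {
      m <- g$members[rows]
      if (!any(m)) next
      eq <- g$eq
      lp <- g$static_lp[rows]
      if (length(g$dyn)) {
        Xd <- resolve_covariates(g$dyn, sub_cohort, sub_state, ctx$centring)
        lp <- lp + drop(Xd %*% eq$coefficients[g$dyn])
      }
      lh <- eq$baseline$log_hazard_intercept + eq$calibration$intercept_shift +
        (eq$baseline$age_slope + eq$calibration$slope_shift) *
          (sub_state$current_age - ctx$centring$age) +
        lp + ctx$log_mult[rows, ei]
      hs[m] <- exp(lh[m])
    }
    if (any(!is.finite(hs))) {
      cvd_error("cvd_numeric_error",
                "non-finite hazard (check the coefficient file)")
    }
    h <- numeric(state$n)
    h[rows] <- hs
    return(h)
  }
  h <- numeric(state$n)
  for (g in ctx$groups[[endpoint]]) {
    rows_l <- sel & g$members
    if (!any(rows_l)) next
    eq <- g$eq
    lp <- g$static_lp
    if (length(g$dyn)) {
      Xd <- resolve_covariates(g$dyn, ctx$cohort, state, ctx$centring)
      lp <- lp + drop(Xd %*% eq$coefficients[g$dyn])
    }
    lh <- eq$baseline$log_hazard_intercept + eq$calibration$intercept_shift +
      (eq$baseline$age_slope + eq$calibration$slope_shift) *
        (state$current_age - ctx$centring$age) +
      lp + ctx$log_mult[, ei]
    h[rows_l] <- exp(lh[rows_l])
  }
  if (any(!is.finite(h[sel]))) {
    cvd_error("cvd_numeric_error",
              "non-finite hazard (check the coefficient file)")
  }
  h
}

#' Model-internal 10-year major-vascular-event risk (Monte Carlo)
#'
#' Monte-Carlo estimate of the 10-year cumulative incidence of a first major
#' vascular event (MI, stroke, coronary revascularisation or vascular death)
#' for one individual, obtained by running the microsimulation restricted to
#' a 10-year horizon.
#'
#' @param profile single-row validated cohort.
#' @param coefset `coefficient_set`.
#' @param reps number of microsimulation replicates (>= 1).
#' @param seed master seed.
#' @return risk in percent.
#' @export
ten_year_mve_risk <- function(profile, coefset, reps = 500, seed = 1) {
  stopifnot(nrow(profile) == 1, reps >= 1)
  cfg <- sim_config(replicates = reps, horizon = 10, master_seed = seed)
  s <- run_microsimulation(profile, coefset, cfg)
  100 * s$person$mve_prob
}

#' Deterministic 10-year major-vascular-event risk score
#'
#' A fast deterministic approximation to the model's 10-year MVE risk:
#' `1 - exp(-H)` with `H` the total major-vascular-event hazard accumulated
#' over ten one-year cycles from the baseline state (no event-history
#' feedback, no competing nonvascular mortality). Used as the default internal
#' risk source for treatment-eligibility screening of whole cohorts, where an
#' externally supplied score is absent.
#'
#' @param cohort validated cohort.
#' @param coefset `coefficient_set`.
#' @return risk in percent, one value per person.
#' @export
ten_year_risk_score <- function(cohort, coefset) {
  ctx <- build_sim_context(cohort, coefset)
  state <- new_sim_state(cohort)
  all_sel <- rep(TRUE, state$n)
  H <- numeric(state$n)
  for (y in 1:10) {
    for (e in MVE_ENDPOINTS) H <- H + ctx_hazard(ctx, state, e, all_sel)
    state$current_age <- state$current_age + 1
  }
  100 * (-expm1(-H))
}
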