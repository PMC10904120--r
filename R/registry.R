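#' @keywords internal
"_PACKAGE"

## Model endpoints, in canonical order. The first five are non-fatal first
## occurrences; the last two are absorbing death causes.
ENDPOINTS <- c("mi", "stroke", "crv", "cancer", "diabetes",
               "vascular_death", "nonvascular_death")
EVENT_ENDPOINTS <- ENDPOINTS[1:5]
DEATH_ENDPOINTS <- ENDPOINTS[6:7]
POOLED_ENDPOINTS <- c("cancer", "diabetes")  # fitted across all participants
MVE_ENDPOINTS <- c("mi", "stroke", "crv", "vascular_death")

POPULATIONS <- c("no_cvd", "cvd", "pooled")

SEX_LEVELS <- c("male", "female")
ETHNICITY_LEVELS <- c("white", "black", "south_asian", "other")
SMOKING_LEVELS <- c("never", "ex", "current")
BMI_LEVELS <- c("<18.5", "18.5-25", "25-30", "30-35", "35-40", "40+")
DIABETES_LEVELS <- c("none", "type1", "type2")
PA_LEVELS <- c("high", "moderate", "low", "missing")
CVD_HISTORY_FLAGS <- c("cvd_mi", "cvd_stroke", "cvd_crv", "cvd_pad", "cvd_other_chd")

## Worst EQ-5D-3L health state / full health utility bounds.
UTILITY_MIN <- -0.594
UTILITY_MAX <- 1.0

AGE_CAP <- 110

#' Default centring constants for continuous covariates
#'
#' Continuous covariates enter the risk and utility equations centred so that
#' the baseline intercept refers to an interpretable reference individual.
#' Coefficient files are self-describing: they carry their own centring block,
#' for which these are the defaults (chosen near the cohort means of a
#' contemporary UK middle-aged population).
#'
#' @return Named list of centring constants (age in years, lipids in mmol/L,
#'   HbA1c in mmol/mol, creatinine in umol/L, blood pressure in mmHg).
#' @export
default_centring <- function() {
  list(age = 60, ldl = 3.6, hdl = 1.5, hba1c = 36,
       creatinine = 71, sbp = 138, dbp = 81)
}

cvd_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "cvd_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

## ---------------------------------------------------------------------------
## Covariate registry
##
## A single versioned dictionary shared by the risk engine, the QoL model, the
## estimation module and the synthetic-data generators. Each entry resolves a
## named covariate to a numeric vector given a cohort (one row per person) and,
## for dynamic covariates, a simulation state. Dynamic covariates depend on the
## time-updated state (event flags, ages, durations); static covariates depend
## on the baseline profile only.
## ---------------------------------------------------------------------------

flag_col <- function(state, endpoint) state$flags[, endpoint]

registry_entries <- function() {
  st <- function(f) list(dynamic = FALSE, resolve = f)
  dy <- function(f) list(dynamic = TRUE, resolve = f)
  ind <- function(x) as.numeric(x)

  ## diabetes presence: at entry or incident during simulation
  diab_now <- function(cohort, state) {
    if (is.null(state)) cohort$diabetes != "none"
    else cohort$diabetes != "none" | flag_col(state, "diabetes") > 0L
  }
  diab_dur <- function(cohort, state) {
    dur <- ifelse(cohort$diabetes != "none", cohort$diabetes_years, NA_real_)
    if (!is.null(state)) {
      dur <- ifelse(!is.na(state$diabetes_duration), state$diabetes_duration, dur)
    }
    dur
  }

  list(
    ## -- static profile covariates ------------------------------------------
    male = st(function(c, s, ct) ind(c$sex == "male")),
    eth_black = st(function(c, s, ct) ind(c$ethnicity == "black")),
    eth_south_asian = st(function(c, s, ct) ind(c$ethnicity == "south_asian")),
    eth_other = st(function(c, s, ct) ind(c$ethnicity == "other")),
    smoke_ex = st(function(c, s, ct) ind(c$smoking == "ex")),
    smoke_current = st(function(c, s, ct) ind(c$smoking == "current")),
    bmi_lt18_5 = st(function(c, s, ct) ind(c$bmi_category == "<18.5")),
    bmi_25_30 = st(function(c, s, ct) ind(c$bmi_category == "25-30")),
    bmi_30_35 = st(function(c, s, ct) ind(c$bmi_category == "30-35")),
    bmi_35_40 = st(function(c, s, ct) ind(c$bmi_category == "35-40")),
    bmi_40plus = st(function(c, s, ct) ind(c$bmi_category == "40+")),
    ldl = st(function(c, s, ct) c$ldl - ct$ldl),
    hdl = st(function(c, s, ct) c$hdl - ct$hdl),
    creatinine = st(function(c, s, ct) c$creatinine - ct$creatinine),
    sbp = st(function(c, s, ct) c$sbp - ct$sbp),
    dbp = st(function(c, s, ct) c$dbp - ct$dbp),
    treated_hypertension = st(function(c, s, ct) ind(c$treated_hypertension == 1)),
    severe_mental_illness = st(function(c, s, ct) ind(c$severe_mental_illness == 1)),
    diet_unhealthy = st(function(c, s, ct) ind(c$diet_unhealthy == 1)),
    pa_moderate = st(function(c, s, ct) ind(c$physical_activity == "moderate")),
    pa_low = st(function(c, s, ct) ind(c$physical_activity == "low")),
    pa_missing = st(function(c, s, ct) ind(c$physical_activity == "missing")),
    statin_at_entry = st(function(c, s, ct) ind(c$statin_at_entry == 1)),
    ## deprivation: linear in quintile steps above quintile 1, plus dummies
    townsend = st(function(c, s, ct) as.numeric(c$townsend_quintile) - 1),
    townsend_q2 = st(function(c, s, ct) ind(c$townsend_quintile == 2)),
    townsend_q3 = st(function(c, s, ct) ind(c$townsend_quintile == 3)),
    townsend_q4 = st(function(c, s, ct) ind(c$townsend_quintile == 4)),
    townsend_q5 = st(function(c, s, ct) ind(c$townsend_quintile == 5)),
    ## baseline CVD history terms (for the secondary-prevention equations)
    hist_mi = st(function(c, s, ct) ind(c$cvd_mi == 1)),
    hist_stroke = st(function(c, s, ct) ind(c$cvd_stroke == 1)),
    hist_crv = st(function(c, s, ct) ind(c$cvd_crv == 1)),
    hist_pad = st(function(c, s, ct) ind(c$cvd_pad == 1)),
    hist_other_chd = st(function(c, s, ct) ind(c$cvd_other_chd == 1)),

    ## -- dynamic event-history covariates (incident, first occurrences) -----
    mi_this_year = dy(function(c, s, ct) ind(flag_col(s, "mi") == 1L)),
    mi_prior_years = dy(function(c, s, ct) ind(flag_col(s, "mi") == 2L)),
    stroke_this_year = dy(function(c, s, ct) ind(flag_col(s, "stroke") == 1L)),
    stroke_prior_years = dy(function(c, s, ct) ind(flag_col(s, "stroke") == 2L)),
    crv_this_year = dy(function(c, s, ct) ind(flag_col(s, "crv") == 1L)),
    crv_prior_years = dy(function(c, s, ct) ind(flag_col(s, "crv") == 2L)),
    crv_any = dy(function(c, s, ct)
      ind(c$cvd_crv == 1 | flag_col(s, "crv") > 0L)),
    cancer_any = dy(function(c, s, ct)
      ind(c$cancer_history == 1 | flag_col(s, "cancer") > 0L)),
    diabetes_lt10 = dy(function(c, s, ct) {
      dur <- diab_dur(c, s); ind(diab_now(c, s) & !is.na(dur) & dur < 10)
    }),
    diabetes_ge10 = dy(function(c, s, ct) {
      dur <- diab_dur(c, s); ind(diab_now(c, s) & !is.na(dur) & dur >= 10)
    }),
    ## HbA1c effect applies only in those without diagnosed diabetes
    hba1c_nondiab = dy(function(c, s, ct)
      (c$hba1c - ct$hba1c) * as.numeric(!diab_now(c, s))),
    age_current = dy(function(c, s, ct) {
      if (is.null(s)) c$age_entry - ct$age else s$current_age - ct$age
    }),

    ## -- utility-model phase covariates (aliases with baseline history folded
    ##    into the "subsequent years" phase) ---------------------------------
    mi_year_of_event = dy(function(c, s, ct) ind(flag_col(s, "mi") == 1L)),
    mi_subsequent = dy(function(c, s, ct)
      ind(flag_col(s, "mi") == 2L | (c$cvd_mi == 1 & flag_col(s, "mi") == 0L))),
    stroke_year_of_event = dy(function(c, s, ct) ind(flag_col(s, "stroke") == 1L)),
    stroke_subsequent = dy(function(c, s, ct)
      ind(flag_col(s, "stroke") == 2L |
            (c$cvd_stroke == 1 & flag_col(s, "stroke") == 0L))),
    diabetes_first_10y = dy(function(c, s, ct) {
      dur <- diab_dur(c, s); ind(diab_now(c, s) & !is.na(dur) & dur < 10)
    }),
    diabetes_after_10y = dy(function(c, s, ct) {
      dur <- diab_dur(c, s); ind(diab_now(c, s) & !is.na(dur) & dur >= 10)
    })
  )
}

.registry <- NULL

#' The shared covariate dictionary
#'
#' Returns the versioned registry of covariate names understood by all
#' modules: coefficient files may only use these keys, and the same resolvers
#' serve the simulation engine, the utility model, episode-split model fitting
#' and the synthetic-data generators. This single registry prevents silent key
#' mismatches between fitted coefficients and simulated covariates.
#'
#' @return Named list; each element has `dynamic` (logical: does the covariate
#'   depend on the time-updated simulation state?) and `resolve`, a function
#'   `(cohort, state, centring) -> numeric`.
#' @export
covariate_registry <- function() {
  if (is.null(.registry)) {
    utils::assignInMyNamespace(".registry", registry_entries())
  }
  .registry
}

#' List known covariate names
#' @param dynamic if not `NULL`, restrict to dynamic (`TRUE`) or static
#'   (`FALSE`) covariates.
#' @return character vector of registry keys.
#' @export
covariate_names <- function(dynamic = NULL) {
  reg <- covariate_registry()
  nm <- names(reg)
  if (!is.null(dynamic)) nm <- nm[vapply(reg, `[[`, TRUE, "dynamic") == dynamic]
  nm
}

#' Resolve covariates to a design matrix
#'
#' @param names covariate names drawn from [covariate_registry()].
#' @param cohort validated cohort data frame (see [read_cohort()]).
#' @param state optional simulation state ([new_sim_state()]); required when
#'   any requested covariate is dynamic. With `state = NULL`, dynamic
#'   covariates are resolved from the baseline profile (entry histories, entry
#'   age), which is the correct behaviour for survey-style data.
#' @param centring centring constants, see [default_centring()].
#' @return numeric matrix, one column per requested covariate.
#' @export
resolve_covariates <- function(names, cohort, state = NULL,
                               centring = default_centring()) {
  reg <- covariate_registry()
  unknown <- setdiff(names, base::names(reg))
  if (length(unknown)) {
    cvd_error("cvd_config_error",
              paste0("unknown covariate name(s): ",
                     paste(unknown, collapse = ", ")))
  }
  n <- nrow(cohort)
  out <- matrix(0, n, length(names), dimnames = list(NULL, names))
  for (nm in names) {
    e <- reg[[nm]]
    if (e$dynamic && is.null(state)) {
      ## baseline stand-in state: entry histories only
      state0 <- new_sim_state(cohort)
      out[, nm] <- e$resolve(cohort, state0, centring)
    } else {
      out[, nm] <- e$resolve(cohort, state, centring)
    }
  }
  out
}

clamp_utility <- function(u) pmin(pmax(u, UTILITY_MIN), UTILITY_MAX)

## Deterministic seed derivation for reproducible substreams. Mixes the master
## seed with stream labels via an LCG-style hash kept inside 32-bit range.
derive_seed <- function(master, ...) {
  ks <- c(master, ...)
  h <- 0
  for (k in ks) h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(h)
}
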