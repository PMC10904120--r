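## ---------------------------------------------------------------------------
## Risk equations, QoL model and coefficient sets, with JSON (de)serialization.
## A full coefficient set resolves every endpoint for both primary- and
## secondary-prevention individuals, plus the utility model; bootstrap
## replicates of the same structure form a PSA ensemble.
## ---------------------------------------------------------------------------

#' Construct a parametric proportional-hazards risk equation
#'
#' One equation per endpoint/population: a Gompertz baseline on current age
#' (log hazard linear in age, centred at the coefficient file's age centring
#' constant), a named map of log hazard ratios over registry covariates, and
#' additive calibration shifts on the log baseline.
#'
#' @param endpoint one of `mi, stroke, crv, cancer, diabetes, vascular_death,
#'   nonvascular_death`.
#' @param population `no_cvd`, `cvd`, or `pooled` (incident cancer and
#'   diabetes equations are fitted across all participants).
#' @param log_hazard_intercept log annual hazard at the centred age for a
#'   reference-level individual.
#' @param age_slope increment in log hazard per year of age.
#' @param coefficients named numeric vector/list of log hazard ratios; names
#'   must come from [covariate_registry()].
#' @param intercept_shift,slope_shift additive calibration terms on the log
#'   baseline (default 0).
#' @param se optional named standard errors; `loglik` optional fit log
#'   likelihood (attached by [fit_risk_equation()]).
#' @return object of class `risk_equation`.
#' @export
risk_equation <- function(endpoint, population, log_hazard_intercept,
                          age_slope = 0, coefficients = numeric(0),
                          intercept_shift = 0, slope_shift = 0,
                          se = NULL, loglik = NULL) {
  if (!endpoint %in% ENDPOINTS) {
    cvd_error("cvd_config_error", paste0("unknown endpoint: ", endpoint))
  }
  if (!population %in% POPULATIONS) {
    cvd_error("cvd_config_error", paste0("unknown population: ", population))
  }
  if (endpoint %in% POOLED_ENDPOINTS && population != "pooled") {
    cvd_error("cvd_config_error",
              paste0(endpoint, " equation must have population = 'pooled'"))
  }
  cf <- unlist(coefficients)
  if (length(cf)) {
    if (is.null(names(cf)) || any(names(cf) == "")) {
      cvd_error("cvd_config_error", "coefficients must be named")
    }
    unknown <- setdiff(names(cf), covariate_names())
    if (length(unknown)) {
      cvd_error("cvd_config_error",
                paste0("equation ", endpoint, "/", population,
                       " uses unknown covariate(s): ",
                       paste(unknown, collapse = ", ")))
    }
    if (any(!is.finite(cf))) {
      cvd_error("cvd_parse_error", "non-numeric or non-finite coefficient")
    }
  }
  for (v in c(log_hazard_intercept, age_slope, intercept_shift, slope_shift)) {
    if (!is.numeric(v) || !is.finite(v)) {
      cvd_error("cvd_parse_error", "baseline parameters must be finite numbers")
    }
  }
  structure(list(endpoint = endpoint, population = population,
                 baseline = list(log_hazard_intercept = log_hazard_intercept,
                                 age_slope = age_slope),
                 coefficients = cf,
                 calibration = list(intercept_shift = intercept_shift,
                                    slope_shift = slope_shift),
                 se = se, loglik = loglik),
            class = "risk_equation")
}

#' Construct an EQ-5D utility model
#'
#' Linear model of EQ-5D utility on registry covariates, with the event-phase
#' decrement structure (year-of-event vs subsequent years for MI and stroke,
#' diabetes split at 10 years of duration, any-cancer decrement). Predictions
#' are clamped to the EQ-5D-3L range `[-0.594, 1]`.
#'
#' @param intercept utility for the reference individual at the centred age.
#' @param coefficients named utility increments/decrements over registry
#'   covariates.
#' @param se optional named standard errors; `sigma` optional residual SD.
#' @return object of class `qol_model`.
#' @export
qol_model <- function(intercept, coefficients = numeric(0), se = NULL,
                      sigma = NULL) {
  cf <- unlist(coefficients)
  if (length(cf)) {
    unknown <- setdiff(names(cf), covariate_names())
    if (length(unknown)) {
      cvd_error("cvd_config_error",
                paste0("QoL model uses unknown covariate(s): ",
                       paste(unknown, collapse = ", ")))
    }
  }
  if (!is.finite(intercept)) cvd_error("cvd_parse_error", "non-finite intercept")
  structure(list(intercept = intercept, coefficients = cf,
                 bounds = c(UTILITY_MIN, UTILITY_MAX), se = se, sigma = sigma),
            class = "qol_model")
}

## endpoint/population combinations a complete set must resolve
required_equations <- function() {
  ep <- setdiff(ENDPOINTS, POOLED_ENDPOINTS)
  rbind(data.frame(endpoint = ep, population = "no_cvd"),
        data.frame(endpoint = ep, population = "cvd"),
        data.frame(endpoint = POOLED_ENDPOINTS, population = "pooled"))
}

eq_key <- function(endpoint, population) paste(endpoint, population, sep = ".")

#' Assemble a complete coefficient set
#'
#' A full model: risk equations covering all seven endpoints for both
#' primary- and secondary-prevention individuals (pooled equations for
#' incident cancer and diabetes), the utility model, centring constants, and
#' a replicate id (0 = point estimate, k >= 1 = bootstrap replicate).
#'
#' @param equations list of [risk_equation()] objects.
#' @param qol a [qol_model()].
#' @param centring named list of centring constants; see [default_centring()].
#' @param replicate_id integer >= 0.
#' @param version schema version string.
#' @return object of class `coefficient_set`; equations keyed
#'   `"<endpoint>.<population>"`.
#' @export
coefficient_set <- function(equations, qol, centring = default_centring(),
                            replicate_id = 0, version = "1.0") {
  eqs <- list()
  for (eq in equations) {
    if (!inherits(eq, "risk_equation")) {
      cvd_error("cvd_config_error", "equations must be risk_equation objects")
    }
    key <- eq_key(eq$endpoint, eq$population)
    if (!is.null(eqs[[key]])) {
      cvd_error("cvd_config_error", paste0("duplicate equation: ", key))
    }
    eqs[[key]] <- eq
  }
  req <- required_equations()
  missing <- req[!(eq_key(req$endpoint, req$population) %in% names(eqs)), ]
  if (nrow(missing)) {
    cvd_error("cvd_completeness_error",
              paste0("missing equation(s): ",
                     paste(eq_key(missing$endpoint, missing$population),
                           collapse = ", ")))
  }
  if (!inherits(qol, "qol_model")) {
    cvd_error("cvd_config_error", "qol must be a qol_model")
  }
  need_ct <- names(default_centring())
  miss_ct <- setdiff(need_ct, names(centring))
  if (length(miss_ct)) {
    cvd_error("cvd_config_error",
              paste0("centring constants missing: ",
                     paste(miss_ct, collapse = ", ")))
  }
  structure(list(version = version, replicate_id = as.integer(replicate_id),
                 centring = centring[need_ct], equations = eqs, qol = qol),
            class = "coefficient_set")
}

#' Look up the equation applying to an endpoint/population
#' @param coefset a `coefficient_set`.
#' @param endpoint endpoint name.
#' @param population `"no_cvd"` or `"cvd"`; pooled endpoints resolve to the
#'   pooled equation for either.
#' @return a `risk_equation`.
#' @export
get_equation <- function(coefset, endpoint, population) {
  pop <- if (endpoint %in% POOLED_ENDPOINTS) "pooled" else population
  eq <- coefset$equations[[eq_key(endpoint, pop)]]
  if (is.null(eq)) {
    cvd_error("cvd_completeness_error",
              paste0("no equation for ", endpoint, "/", pop))
  }
  eq
}

#' Read a coefficient-set JSON file
#'
#' The document must carry `version`, `centring`, the complete `equations`
#' array and a `qol` block; unknown covariate names and non-numeric
#' coefficients are rejected, and an incomplete set of equations is a
#' completeness error.
#'
#' @param path JSON file path.
#' @return `coefficient_set`.
#' @export
read_coefficients <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    cvd_error("cvd_parse_error",
                              paste0("cannot parse JSON: ", conditionMessage(e))))
  if (is.null(doc$version)) {
    cvd_error("cvd_schema_error", "coefficient file missing 'version' field")
  }
  num1 <- function(x, what) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1) {
      cvd_error("cvd_parse_error", paste0("expected a number for ", what))
    }
    x
  }
  eqs <- lapply(doc$equations, function(e) {
    cf <- e$coefficients
    if (length(cf)) {
      ok <- vapply(cf, function(x) is.numeric(x) && length(x) == 1, TRUE)
      if (!all(ok)) {
        cvd_error("cvd_parse_error",
                  paste0("non-numeric coefficient in ", e$endpoint))
      }
    }
    risk_equation(
      endpoint = e$endpoint, population = e$population,
      log_hazard_intercept = num1(e$baseline$log_hazard_intercept,
                                  "baseline.log_hazard_intercept"),
      age_slope = num1(e$baseline$age_slope, "baseline.age_slope"),
      coefficients = cf,
      intercept_shift =
        if (is.null(e$calibration)) 0
        else num1(e$calibration$intercept_shift, "calibration.intercept_shift"),
      slope_shift =
        if (is.null(e$calibration)) 0
        else num1(e$calibration$slope_shift, "calibration.slope_shift"))
  })
  q <- doc$qol
  if (is.null(q)) cvd_error("cvd_schema_error", "coefficient file missing 'qol'")
  qol <- qol_model(intercept = num1(q$intercept, "qol.intercept"),
                   coefficients = q$coefficients)
  coefficient_set(eqs, qol,
                  centring = lapply(doc$centring, as.numeric),
                  replicate_id = if (is.null(doc$replicate_id)) 0
                                 else doc$replicate_id,
                  version = doc$version)
}

#' Write a coefficient set to JSON
#' @param coefset `coefficient_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coefset, path) {
  doc <- list(
    version = coefset$version,
    replicate_id = coefset$replicate_id,
    centring = coefset$centring,
    equations = lapply(unname(coefset$equations), function(e) {
      list(endpoint = e$endpoint, population = e$population,
           baseline = e$baseline,
           calibration = e$calibration,
           coefficients = as.list(e$coefficients))
    }),
    qol = list(intercept = coefset$qol$intercept,
               coefficients = as.list(coefset$qol$coefficients)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set> version", x$version,
      "replicate", x$replicate_id, "\n")
  for (k in names(x$equations)) {
    e <- x$equations[[k]]
    cat(sprintf("  %-28s b0=%8.4f slope=%7.4f shift=%7.4f  %d covariates\n",
                k, e$baseline$log_hazard_intercept, e$baseline$age_slope,
                e$calibration$intercept_shift, length(e$coefficients)))
  }
  cat(sprintf("  qol: intercept %.3f, %d covariates\n",
              x$qol$intercept, length(x$qol$coefficients)))
  invisible(x)
}
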