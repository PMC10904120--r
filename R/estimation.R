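## ---------------------------------------------------------------------------
## Estimation and calibration: Gompertz proportional-hazards risk equations
## fitted to individual-participant follow-up data by yearly episode-split
## person-period Poisson regression (piecewise-exponential equivalence, age
## term at the episode midpoint); bootstrap ensembles; baseline recalibration
## against observed cumulative incidence; predicted-vs-observed validation.
## ---------------------------------------------------------------------------

#' Construct a follow-up dataset
#'
#' Individual-participant data for estimation and validation: the baseline
#' cohort, a long table of first-occurrence event times, and each person's
#' follow-up end (death or censoring).
#'
#' @param cohort validated cohort.
#' @param events data frame with columns `person_id`, `endpoint`, `time`
#'   (years from entry); first occurrences only.
#' @param end_time numeric vector aligned with `cohort`: follow-up end in
#'   years (death time if the person died, censoring time otherwise).
#' @return object of class `followup`.
#' @export
followup_data <- function(cohort, events, end_time) {
  stopifnot(length(end_time) == nrow(cohort))
  if (nrow(events)) {
    stopifnot(all(c("person_id", "endpoint", "time") %in% names(events)))
    if (!all(events$endpoint %in% ENDPOINTS)) {
      cvd_error("cvd_validation_error", "unknown endpoint in events")
    }
    et <- end_time[match(events$person_id, cohort$person_id)]
    if (any(events$time > et + 1e-9)) {
      cvd_error("cvd_validation_error", "event time after follow-up end")
    }
  }
  structure(list(cohort = cohort,
                 events = as.data.frame(events),
                 end_time = as.numeric(end_time)),
            class = "followup")
}

## first-occurrence time of each endpoint per person, n x 7 (NA = never)
event_time_matrix <- function(ipd) {
  n <- nrow(ipd$cohort)
  m <- matrix(NA_real_, n, length(ENDPOINTS),
              dimnames = list(NULL, ENDPOINTS))
  if (nrow(ipd$events)) {
    pi <- match(ipd$events$person_id, ipd$cohort$person_id)
    ei <- match(ipd$events$endpoint, ENDPOINTS)
    ord <- order(ipd$events$time, decreasing = TRUE)  # earliest wins last
    for (k in ord) m[pi[k], ei[k]] <- ipd$events$time[k]
  }
  m
}

population_rows <- function(cohort, population) {
  switch(population,
         no_cvd = !has_cvd_history(cohort),
         cvd = has_cvd_history(cohort),
         pooled = rep(TRUE, nrow(cohort)),
         cvd_error("cvd_config_error",
                   paste0("unknown population: ", population)))
}

## yearly episode-split person-period data for one endpoint, with extra cuts
## at other-event times so time-updated history covariates are exact
episode_split <- function(ipd, endpoint, population, covariates, centring) {
  cohort <- ipd$cohort
  etm <- event_time_matrix(ipd)
  rows <- which(population_rows(cohort, population))
  ## not at risk of a first occurrence if the endpoint is in baseline history
  base_hist <- switch(endpoint,
                      mi = cohort$cvd_mi == 1, stroke = cohort$cvd_stroke == 1,
                      crv = cohort$cvd_crv == 1,
                      cancer = cohort$cancer_history == 1,
                      diabetes = cohort$diabetes != "none",
                      rep(FALSE, nrow(cohort)))
  rows <- rows[!base_hist[rows]]
  if (!length(rows)) {
    cvd_error("cvd_estimation_error", "no one at risk for this endpoint")
  }
  own <- etm[rows, endpoint]
  exit <- pmin(ifelse(is.na(own), Inf, own), ipd$end_time[rows])
  ev <- !is.na(own) & own <= ipd$end_time[rows] + 1e-9
  other <- etm[rows, setdiff(ENDPOINTS, endpoint), drop = FALSE]
  seg_p <- seg_a <- seg_b <- seg_e <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    xe <- exit[i]
    if (xe <= 0) next
    cuts <- c(seq(0, ceiling(xe)), other[i, ])
    cuts <- sort(unique(cuts[!is.na(cuts) & cuts < xe]))
    a <- cuts
    b <- c(cuts[-1], xe)
    keep <- b > a
    seg_p[[i]] <- rep.int(i, sum(keep))
    seg_a[[i]] <- a[keep]
    seg_b[[i]] <- b[keep]
    e <- rep(0L, sum(keep))
    if (ev[i]) e[length(e)] <- 1L
    seg_e[[i]] <- e
  }
  pidx <- unlist(seg_p)
  if (!length(pidx)) {
    cvd_error("cvd_estimation_error", "no follow-up time for this endpoint")
  }
  tstart <- unlist(seg_a); tstop <- unlist(seg_b); event <- unlist(seg_e)
  seg_cohort <- cohort[rows[pidx], , drop = FALSE]
  class(seg_cohort) <- class(cohort)
  ## reconstruct the dynamic state at each segment start
  ns <- length(pidx)
  state <- new_sim_state(seg_cohort)
  state$current_age <- seg_cohort$age_entry + (tstart + tstop) / 2
  yr <- floor(tstart)
  for (e2 in EVENT_ENDPOINTS) {
    if (e2 == endpoint) next
    te <- etm[rows[pidx], e2]
    this_yr <- !is.na(te) & floor(te) == yr & te <= tstart + 1e-12
    prior <- !is.na(te) & floor(te) < yr
    state$flags[this_yr, e2] <- 1L
    state$flags[prior, e2] <- 2L
    state$years_since[prior, e2] <- yr[prior] - floor(te[prior])
    state$years_since[this_yr, e2] <- 0
    if (e2 == "diabetes") {
      inc <- this_yr | prior
      state$diabetes_duration[inc] <- yr[inc] - floor(te[inc])
      state$diabetes_type[inc] <- "type2"
    }
  }
  ## prevalent diabetes duration advances with follow-up time
  prev_d <- seg_cohort$diabetes != "none"
  state$diabetes_duration[prev_d] <-
    seg_cohort$diabetes_years[prev_d] + yr[prev_d]
  X <- resolve_covariates(covariates, seg_cohort, state, centring)
  list(X = X, event = event, exposure = tstop - tstart,
       person = rows[pidx], tstart = tstart, tstop = tstop)
}

#' Fit a Gompertz proportional-hazards risk equation
#'
#' Maximum-likelihood fit on the age timescale via yearly episode-split
#' person-period Poisson regression with a log-exposure offset (the standard
#' piecewise-exponential representation; the Gompertz age term uses the
#' episode midpoint age). Time-updated event-history covariates are handled
#' by additional episode cuts at event times. Covariates constant across all
#' episodes are dropped with a warning and recorded in the result.
#'
#' @param ipd a [followup_data()] object.
#' @param endpoint endpoint to fit.
#' @param population `no_cvd`, `cvd` or `pooled`.
#' @param covariates registry covariate names for the linear predictor.
#' @param include_age include the Gompertz log-linear age slope
#'   (default `TRUE`).
#' @param centring centring constants.
#' @return a [risk_equation()] with standard errors (`$se`, including
#'   `(Intercept)` and `age_current`) and `$loglik`; dropped covariates in
#'   attribute `dropped`.
#' @export
fit_risk_equation <- function(ipd, endpoint, population,
                              covariates = character(0), include_age = TRUE,
                              centring = default_centring()) {
  all_cov <- c(if (include_age) "age_current", covariates)
  es <- episode_split(ipd, endpoint, population, all_cov, centring)
  if (sum(es$event) < 1) {
    cvd_error("cvd_estimation_error",
              paste0("no ", endpoint, " events in the ", population,
                     " data subset"))
  }
  X <- es$X
  dropped <- character(0)
  if (ncol(X)) {
    const <- apply(X, 2, function(v) max(v) - min(v) == 0)
    if (any(const)) {
      dropped <- colnames(X)[const]
      warning("dropping constant covariate(s): ",
              paste(dropped, collapse = ", "))
      X <- X[, !const, drop = FALSE]
    }
  }
  df <- data.frame(.events = es$event, .off = log(es$exposure))
  fml <- ".events ~ offset(.off)"
  if (ncol(X)) {
    df <- cbind(df, as.data.frame(X))
    fml <- paste(fml, "+", paste(colnames(X), collapse = " + "))
  }
  fit <- stats::glm(stats::as.formula(fml), family = stats::poisson(), data = df,
                    control = stats::glm.control(maxit = 50))
  if (!fit$converged) {
    cvd_error("cvd_estimation_error",
              paste0("Poisson fit did not converge after ", fit$iter,
                     " iterations"))
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  slope <- if (include_age && "age_current" %in% names(cf))
    cf[["age_current"]] else 0
  beta <- cf[setdiff(names(cf), c("(Intercept)", "age_current"))]
  eq <- risk_equation(endpoint, population,
                      log_hazard_intercept = cf[["(Intercept)"]],
                      age_slope = slope,
                      coefficients = beta,
                      se = se,
                      loglik = as.numeric(stats::logLik(fit)))
  attr(eq, "dropped") <- dropped
  attr(eq, "n_events") <- sum(es$event)
  attr(eq, "person_years") <- sum(es$exposure)
  eq
}

#' Fit the complete set of risk equations
#'
#' Fits every endpoint/population combination a [coefficient_set()] requires:
#' separate equations for individuals without and with CVD history, pooled
#' equations for incident cancer and diabetes.
#'
#' @param ipd a [followup_data()] object covering both populations.
#' @param covariates named list mapping each endpoint to its covariate names;
#'   endpoints absent from the list get an age-only baseline.
#' @param qol a [qol_model()] to embed.
#' @param centring centring constants.
#' @param replicate_id replicate id for the resulting set.
#' @return a `coefficient_set`.
#' @export
fit_all_equations <- function(ipd, covariates = list(), qol,
                              centring = default_centring(),
                              replicate_id = 0) {
  req <- required_equations()
  eqs <- lapply(seq_len(nrow(req)), function(i) {
    fit_risk_equation(ipd, req$endpoint[i], req$population[i],
                      covariates = covariates[[req$endpoint[i]]] %||% character(0),
                      centring = centring)
  })
  coefficient_set(eqs, qol, centring = centring, replicate_id = replicate_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap ensemble of coefficient sets
#'
#' Refits the requested equations on `B` person-level resamples with
#' replacement; each resulting set carries `replicate_id` 1..B and inherits
#' every non-refitted component from `base`. Because the person-period
#' episode rows of a resampled person are exactly the original person's
#' rows, the episode split is computed once and each replicate reduces to a
#' Poisson fit on a row resample, which keeps large ensembles cheap.
#' Replicates whose refit fails are skipped with a warning and counted in
#' attribute `n_failed`. Deterministic given `seed`.
#'
#' @param ipd a [followup_data()].
#' @param eqspec list of specs `list(endpoint=, population=, covariates=)`
#'   naming the equations to refit.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param base point-estimate `coefficient_set` supplying everything not
#'   refitted.
#' @param centring centring constants.
#' @return list of `coefficient_set`s (length <= B).
#' @export
bootstrap_ensemble <- function(ipd, eqspec, B, seed, base,
                               centring = default_centring()) {
  stopifnot(B >= 1)
  n <- nrow(ipd$cohort)
  prep <- lapply(eqspec, function(sp) {
    es <- episode_split(ipd, sp$endpoint, sp$population,
                        c("age_current", sp$covariates %||% character(0)),
                        centring)
    X <- cbind(`(Intercept)` = 1, es$X)
    rbp <- vector("list", n)
    spl <- split(seq_along(es$person), es$person)
    rbp[as.integer(names(spl))] <- spl
    ## starting values from the full-data fit speed up replicate fits
    f0 <- stats::glm.fit(X, es$event, family = stats::poisson(),
                         offset = log(es$exposure))
    list(sp = sp, X = X, y = es$event, off = log(es$exposure),
         rows_by_person = rbp, start = f0$coefficients)
  })
  out <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch({
      set_b <- base
      for (pp in prep) {
        rows <- unlist(pp$rows_by_person[idx], use.names = FALSE)
        fit <- suppressWarnings(
          stats::glm.fit(pp$X[rows, , drop = FALSE], pp$y[rows],
                         family = stats::poisson(), offset = pp$off[rows],
                         start = pp$start))
        cf <- fit$coefficients
        if (!fit$converged || anyNA(cf) || sum(pp$y[rows]) < 1) {
          cvd_error("cvd_estimation_error", "replicate fit failed")
        }
        slope <- if ("age_current" %in% names(cf)) cf[["age_current"]] else 0
        beta <- cf[setdiff(names(cf), c("(Intercept)", "age_current"))]
        eq <- risk_equation(pp$sp$endpoint, pp$sp$population,
                            log_hazard_intercept = cf[["(Intercept)"]],
                            age_slope = slope, coefficients = beta)
        set_b$equations[[eq_key(eq$endpoint, eq$population)]] <- eq
      }
      set_b$replicate_id <- b
      set_b
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      warning(sprintf("bootstrap replicate %d failed: %s", b,
                      conditionMessage(res)))
    } else {
      out[[b]] <- res
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  attr(out, "n_failed") <- failed
  out
}

#' Observed cumulative incidence of an endpoint
#'
#' Nonparametric cumulative incidence from follow-up data, by default in the
#' Aalen-Johansen form treating death from other causes as a competing risk
#' (matching the estimand the microsimulation produces); optionally the naive
#' `1 - Kaplan-Meier` variant that censors competing deaths.
#'
#' @param ipd a [followup_data()].
#' @param endpoint endpoint name.
#' @param horizon integer years.
#' @param method `"aalen-johansen"` (default) or `"one-minus-km"`.
#' @param subset optional logical vector selecting persons.
#' @return named numeric vector: cumulative incidence at years `1..horizon`.
#' @export
observed_cumulative_incidence <- function(ipd, endpoint, horizon,
                                          method = c("aalen-johansen",
                                                     "one-minus-km"),
                                          subset = NULL) {
  method <- match.arg(method)
  cohort <- ipd$cohort
  etm <- event_time_matrix(ipd)
  keep <- if (is.null(subset)) rep(TRUE, nrow(cohort)) else subset
  own <- etm[keep, endpoint]
  endt <- ipd$end_time[keep]
  death_t <- pmin(ifelse(is.na(etm[keep, "vascular_death"]), Inf,
                         etm[keep, "vascular_death"]),
                  ifelse(is.na(etm[keep, "nonvascular_death"]), Inf,
                         etm[keep, "nonvascular_death"]))
  has_own <- !is.na(own)
  time <- ifelse(has_own, own, endt)
  died_first <- !has_own & is.finite(death_t) & death_t <= endt + 1e-9
  status <- ifelse(has_own, 1L, ifelse(died_first, 2L, 0L))
  if (endpoint %in% DEATH_ENDPOINTS) {
    ## the endpoint itself is a death cause; status already handles it
  }
  if (!any(status == 1L)) {
    return(stats::setNames(rep(0, horizon), seq_len(horizon)))
  }
  if (method == "one-minus-km") {
    fit <- survival::survfit(survival::Surv(time, status == 1L) ~ 1,
                             se.fit = FALSE)
    s <- summary(fit, times = seq_len(horizon), extend = TRUE)$surv
    return(stats::setNames(1 - s, seq_len(horizon)))
  }
  st <- factor(status, levels = c(0L, 1L, 2L),
               labels = c("censor", "event", "competing"))
  ## point estimates only: the pointwise standard errors are not used and
  ## dominate the cost of survfit on large continuous-time datasets
  fit <- survival::survfit(survival::Surv(time, st) ~ 1, se.fit = FALSE)
  sm <- summary(fit, times = seq_len(horizon), extend = TRUE)
  ci <- sm$pstate[, match("event", fit$states)]
  stats::setNames(ci, seq_len(horizon))
}

#' Calibrate risk-equation baselines to a target cohort
#'
#' Chooses per endpoint (and per population, where the target contains both
#' populations) an additive intercept shift on the log baseline hazard that
#' minimizes the sum over follow-up years of squared differences between
#' model-simulated and observed cumulative incidence. The search iterates
#' multiplicative updates `shift <- shift + log(observed/simulated)` at the
#' final year, re-simulating with common random numbers, and keeps the
#' best-objective shifts visited; the post-calibration discrepancy therefore
#' never exceeds the pre-calibration one.
#'
#' @param coefset starting `coefficient_set`.
#' @param target_ipd [followup_data()] for the calibration target cohort.
#' @param horizon calibration horizon in years (default: ceiling of the
#'   longest follow-up).
#' @param endpoints endpoints to calibrate (default all seven).
#' @param config simulation settings used inside the search (replicates
#'   default 2; the master seed fixes the common random numbers).
#' @param max_iter iteration budget; `tol` convergence tolerance on the
#'   largest absolute update.
#' @return list: `coefset` (with calibration shifts set), `report` (data
#'   frame of shifts and pre/post discrepancy per endpoint/population),
#'   `iterations`, `converged`.
#' @export
calibrate_model <- function(coefset, target_ipd,
                            horizon = ceiling(max(target_ipd$end_time)),
                            endpoints = ENDPOINTS,
                            config = sim_config(replicates = 2, horizon = horizon),
                            max_iter = 10, tol = 0.01) {
  cohort <- target_ipd$cohort
  cvd <- has_cvd_history(cohort)
  ## calibration units: (endpoint, population) with the pooled endpoints
  ## calibrated on the whole cohort
  units <- list()
  for (e in endpoints) {
    if (e %in% POOLED_ENDPOINTS) {
      units[[eq_key(e, "pooled")]] <-
        list(endpoint = e, population = "pooled", rows = rep(TRUE, nrow(cohort)))
    } else {
      if (any(!cvd)) units[[eq_key(e, "no_cvd")]] <-
        list(endpoint = e, population = "no_cvd", rows = !cvd)
      if (any(cvd)) units[[eq_key(e, "cvd")]] <-
        list(endpoint = e, population = "cvd", rows = cvd)
    }
  }
  obs <- lapply(units, function(u)
    observed_cumulative_incidence(target_ipd, u$endpoint, horizon,
                                  subset = u$rows))
  shifts <- vapply(units, function(u)
    get_equation(coefset, u$endpoint, u$population)$calibration$intercept_shift,
    0)
  apply_shifts <- function(cs, sh) {
    for (k in names(units)) {
      u <- units[[k]]
      pop <- if (u$endpoint %in% POOLED_ENDPOINTS) "pooled" else u$population
      cs$equations[[eq_key(u$endpoint, pop)]]$calibration$intercept_shift <- sh[[k]]
    }
    cs
  }
  objective <- function(sh) {
    cs <- apply_shifts(coefset, sh)
    ## simulate each population subgroup once, reuse across its endpoints
    sims <- list()
    for (pop in unique(vapply(units, `[[`, "", "population"))) {
      rows <- if (pop == "pooled") rep(TRUE, nrow(cohort)) else
        population_rows(cohort, pop)
      sub <- cohort[rows, , drop = FALSE]; class(sub) <- class(cohort)
      sims[[pop]] <- run_microsimulation(sub, cs, config)
    }
    obj <- upd <- stats::setNames(numeric(length(units)), names(units))
    for (k in names(units)) {
      u <- units[[k]]
      sim_ci <- incidence_curve(sims[[u$population]], u$endpoint,
                                seq_len(horizon))
      obj[k] <- sum((sim_ci - obs[[k]])^2)
      oH <- obs[[k]][horizon]; sH <- sim_ci[horizon]
      upd[k] <- if (oH <= 0) 0 else if (sH <= 0) 1 else
        max(min(log(oH / sH), 2), -2)
    }
    list(obj = obj, upd = upd)
  }
  ev <- objective(shifts)
  pre <- ev$obj
  best_obj <- ev$obj; best_shifts <- shifts
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    shifts <- shifts + ev$upd
    ev <- objective(shifts)
    improved <- ev$obj < best_obj
    best_shifts[improved] <- shifts[improved]
    best_obj[improved] <- ev$obj[improved]
    if (max(abs(ev$upd)) < tol) { converged <- TRUE; break }
  }
  if (!converged && iter >= max_iter) {
    warning(sprintf("calibration did not converge in %d iterations; %s",
                    max_iter, "returning best-found shifts"))
  }
  report <- data.frame(
    endpoint = vapply(units, `[[`, "", "endpoint"),
    population = vapply(units, `[[`, "", "population"),
    intercept_shift = unname(best_shifts),
    discrepancy_pre = unname(pre),
    discrepancy_post = unname(best_obj),
    row.names = NULL)
  list(coefset = apply_shifts(coefset, best_shifts), report = report,
       iterations = iter, converged = converged)
}

#' Validate model-simulated against observed cumulative incidence
#'
#' Simulates the cohort under the model and pairs the simulated cumulative
#' incidence of each endpoint, year by year, with the observed (Aalen-
#' Johansen) incidence in the follow-up data, overall and within subgroups;
#' per-endpoint horizons accommodate endpoints with shorter follow-up.
#'
#' @param coefset `coefficient_set`.
#' @param ipd observed [followup_data()].
#' @param subgroups named list of logical vectors (or a cohort column name to
#'   split on); empty subgroups are reported as skipped.
#' @param horizon default horizon in years; `endpoint_horizons` a named list
#'   of per-endpoint overrides (e.g. shorter follow-up for incident
#'   diabetes).
#' @param config simulation settings (replicates default 2).
#' @return `cvd_validation`: data frame with columns subgroup, endpoint,
#'   year, observed, predicted, ratio, difference, n_events; skipped
#'   subgroups in attribute `skipped`.
#' @export
validate_model <- function(coefset, ipd, subgroups = NULL,
                           horizon = ceiling(max(ipd$end_time)),
                           endpoint_horizons = list(),
                           config = sim_config(replicates = 2,
                                               horizon = horizon)) {
  cohort <- ipd$cohort
  if (is.character(subgroups) && length(subgroups) == 1) {
    col <- cohort[[subgroups]]
    subgroups <- lapply(stats::setNames(nm = sort(unique(col))),
                        function(v) col == v)
  }
  groups <- c(list(overall = rep(TRUE, nrow(cohort))), subgroups)
  etm <- event_time_matrix(ipd)
  rows <- list(); skipped <- character(0)
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (!any(sel)) { skipped <- c(skipped, g); next }
    sub <- cohort[sel, , drop = FALSE]; class(sub) <- class(cohort)
    sim <- run_microsimulation(sub, coefset, config)
    for (e in ENDPOINTS) {
      h <- min(endpoint_horizons[[e]] %||% horizon, horizon)
      o <- observed_cumulative_incidence(ipd, e, h, subset = sel)
      p <- incidence_curve(sim, e, seq_len(h))
      nev <- vapply(seq_len(h), function(y)
        sum(!is.na(etm[sel, e]) & etm[sel, e] <= y), 0)
      rows[[paste(g, e)]] <- data.frame(
        subgroup = g, endpoint = e, year = seq_len(h),
        observed = unname(o), predicted = unname(p),
        ratio = unname(ifelse(o > 0, p / o, NA_real_)),
        difference = unname(p - o), n_events = nev)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("cvd_validation", "data.frame")
  out
}
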