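## ---------------------------------------------------------------------------
## Annual-cycle microsimulation. Each cycle draws the seven endpoints in a
## uniformly random order; endpoints already in history are skipped (first
## occurrences only); events fired earlier within a cycle feed the hazards of
## endpoints drawn later in the same cycle (so a same-year MI raises same-year
## vascular-death risk); a death aborts the remaining draws. Survivors then
## age one year, year-of-event flags roll to prior-years, and durations
## increment. Simulation continues until death or age 110 or the horizon.
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' @param replicates microsimulation replicates per person (default 500).
#' @param horizon projection horizon in years, or `Inf` for lifetime
#'   (death or age 110).
#' @param master_seed integer master seed; every random draw in a run derives
#'   from it via per-(replicate, cycle) substreams, so runs are bitwise
#'   reproducible and scenario contrasts share common random numbers.
#' @param half_cycle_correction if `TRUE` (default), the death year
#'   contributes half a life year and half its annual utility.
#' @param discount_rate annual discount rate on QALYs and life years
#'   (default 0).
#' @param within_cycle_feedback if `TRUE` (default), events fired earlier in a
#'   cycle update the hazards of endpoints drawn later in the same cycle;
#'   if `FALSE`, all hazards use the start-of-cycle state.
#' @param audit if `TRUE`, per-cycle exposure and utility streams are kept for
#'   accounting checks (memory scales with n x cycles).
#' @return a `sim_config` list.
#' @export
sim_config <- function(replicates = 500, horizon = Inf, master_seed = 1,
                       half_cycle_correction = TRUE, discount_rate = 0,
                       within_cycle_feedback = TRUE, audit = FALSE) {
  stopifnot(replicates >= 1, horizon > 0)
  structure(list(replicates = as.integer(replicates), horizon = horizon,
                 master_seed = as.integer(master_seed),
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 discount_rate = discount_rate,
                 within_cycle_feedback = isTRUE(within_cycle_feedback),
                 audit = isTRUE(audit)),
            class = "sim_config")
}

## random permutations of 1..k for each of n rows, from a n x k uniform matrix
row_permutations <- function(u) {
  n <- nrow(u); k <- ncol(u)
  o <- order(rep.int(seq_len(n), k), as.vector(u))
  matrix((o - 1L) %/% n + 1L, nrow = n, ncol = k, byrow = TRUE)
}

#' Advance the simulation by one annual cycle
#'
#' Draws a fresh uniformly random endpoint order per person, evaluates each
#' endpoint sequentially with its annual event probability given the state as
#' updated so far within the cycle, fires events, and rolls the state to the
#' next year. Exposed for audit and unit testing; [run_microsimulation()] uses
#' the same code path with derived random substreams.
#'
#' @param cohort validated cohort aligned with `state`.
#' @param state a [new_sim_state()] state.
#' @param coefset `coefficient_set`.
#' @param config `sim_config` (controls within-cycle feedback).
#' @param u_perm,u_event optional `n x 7` uniform matrices (drawn from the
#'   session RNG when omitted); `u_event` columns are indexed by endpoint.
#' @param log_mult optional `n x 7` per-person log hazard multipliers
#'   (treatment effects).
#' @return list with the updated `state`, logical `fired` (`n x 7`), the
#'   annual `utility` evaluated after this cycle's events, and `died`.
#' @export
simulate_cycle <- function(cohort, state, coefset, config = sim_config(),
                           u_perm = NULL, u_event = NULL, log_mult = NULL) {
  ctx <- build_sim_context(cohort, coefset, log_mult)
  n <- state$n
  if (is.null(u_perm)) u_perm <- matrix(stats::runif(n * 7), n, 7)
  if (is.null(u_event)) u_event <- matrix(stats::runif(n * 7), n, 7)
  active <- state$alive & state$current_age < AGE_CAP
  advance_cycle(ctx, state, u_perm, u_event, active,
                feedback = config$within_cycle_feedback)
}

advance_cycle <- function(ctx, state, u_perm, u_event, active,
                          feedback = TRUE) {
  n <- state$n
  fired <- matrix(FALSE, n, length(ENDPOINTS),
                  dimnames = list(NULL, ENDPOINTS))
  if (any(active)) {
    perm <- row_permutations(u_perm)
    ## start-of-cycle hazards for every endpoint; within the cycle only the
    ## (rare) persons whose state changed need recomputation
    H0 <- matrix(0, n, length(ENDPOINTS))
    for (ei in seq_along(ENDPOINTS)) {
      H0[, ei] <- ctx_hazard(ctx, state, ENDPOINTS[ei], active)
    }
    dirty <- logical(n)
    for (pos in seq_along(ENDPOINTS)) {
      for (ei in seq_along(ENDPOINTS)) {
        e <- ENDPOINTS[ei]
        sel <- active & state$alive & perm[, pos] == ei
        if (ei <= 5L) {
          sel <- sel & state$flags[, e] == 0L & !ctx$baseline_hist[, e]
        }
        if (!any(sel)) next
        h <- H0[, ei]
        if (feedback) {
          redo <- which(sel & dirty)
          if (length(redo)) {
            h[redo] <- ctx_hazard(ctx, state, e, sel, rows = redo)[redo]
          }
        }
        p <- -expm1(-h)
        hit <- sel & u_event[, ei] < p
        if (!any(hit)) next
        fired[hit, ei] <- TRUE
        if (ei <= 5L) {
          dirty[hit] <- TRUE
          state$flags[hit, e] <- 1L
          state$years_since[hit, e] <- 0
          if (e == "diabetes") {
            state$diabetes_duration[hit] <- 0
            state$diabetes_type[hit] <- "type2"
          }
        } else {
          state$alive[hit] <- FALSE
          state$cause_of_death[hit] <-
            if (e == "vascular_death") "vascular" else "nonvascular"
        }
      }
    }
  }
  ## annual utility, evaluated after this cycle's events (year-of-event
  ## decrements apply), before flags roll to prior-years
  utility <- ctx_utility(ctx, state)
  died <- active & !state$alive
  ## roll to next year
  surv <- active & state$alive
  state$current_age[surv] <- state$current_age[surv] + 1
  rolled <- state$flags == 1L
  rolled[!active, ] <- FALSE
  state$flags[rolled] <- 2L
  prior <- state$flags == 2L & matrix(active, n, 5)
  state$years_since[prior] <- state$years_since[prior] + 1
  has_d <- active & !is.na(state$diabetes_duration)
  state$diabetes_duration[has_d] <- state$diabetes_duration[has_d] + 1
  list(state = state, fired = fired, utility = utility, died = died)
}

## full multi-cycle engine over one replicate
engine_run <- function(ctx, config, replicate) {
  state <- new_sim_state(ctx$cohort)
  n <- state$n
  event_cycle <- matrix(NA_real_, n, length(ENDPOINTS),
                        dimnames = list(NULL, ENDPOINTS))
  ly <- qaly <- ly10 <- qaly10 <- ly20 <- qaly20 <- numeric(n)
  death_cycle <- rep(NA_real_, n)
  audit <- if (config$audit) list() else NULL
  hc <- if (config$half_cycle_correction) 0.5 else 0
  cycle <- 0L
  repeat {
    active <- state$alive & state$current_age < AGE_CAP & cycle < config$horizon
    if (!any(active)) break
    set.seed(derive_seed(config$master_seed, replicate, cycle + 1L))
    u <- matrix(stats::runif(n * 14L), n, 14L)
    res <- advance_cycle(ctx, state, u[, 1:7, drop = FALSE],
                         u[, 8:14, drop = FALSE], active,
                         feedback = config$within_cycle_feedback)
    state <- res$state
    newly <- res$fired & is.na(event_cycle)
    event_cycle[newly] <- cycle
    death_cycle[res$died] <- cycle
    exposure <- numeric(n)
    exposure[active & state$alive] <- 1
    exposure[res$died] <- hc
    disc <- (1 + config$discount_rate)^(-cycle)
    ly <- ly + exposure * disc
    qaly <- qaly + exposure * res$utility * disc
    if (cycle < 10) { ly10 <- ly10 + exposure; qaly10 <- qaly10 + exposure * res$utility }
    if (cycle < 20) { ly20 <- ly20 + exposure; qaly20 <- qaly20 + exposure * res$utility }
    if (config$audit) {
      audit[[cycle + 1L]] <- list(exposure = exposure, utility = res$utility)
    }
    cycle <- cycle + 1L
  }
  mve <- rowSums(!is.na(event_cycle[, MVE_ENDPOINTS, drop = FALSE])) > 0
  list(event_cycle = event_cycle, death_cycle = death_cycle,
       cause_of_death = state$cause_of_death, ly = ly, qaly = qaly,
       ly10 = ly10, qaly10 = qaly10, ly20 = ly20, qaly20 = qaly20,
       mve = mve, cycles = cycle, state = state, audit = audit)
}

#' Simulate one individual's remaining lifetime
#'
#' Repeated annual cycles until death, age 110, or the configured horizon;
#' survivors at the cap are censored alive. Life years count complete cycles
#' survived plus (with the half-cycle correction, on by default) half the
#' death year; QALYs accumulate the annual utility stream under the same
#' convention.
#'
#' @param profile single-row validated cohort.
#' @param coefset `coefficient_set`.
#' @param config `sim_config` (a single replicate is run; use
#'   [run_microsimulation()] for replicate averages).
#' @param log_mult optional `1 x 7` log hazard multiplier matrix.
#' @return a `trajectory` list: per-endpoint first-occurrence years (from
#'   entry, `NA` if never), `death_year`, `cause_of_death`, `life_years`,
#'   `qalys`, and (when `config$audit`) the per-cycle utility stream.
#' @export
simulate_individual <- function(profile, coefset, config = sim_config(),
                                log_mult = NULL) {
  stopifnot(nrow(profile) == 1)
  ctx <- build_sim_context(profile, coefset, log_mult)
  r <- engine_run(ctx, config, replicate = 1L)
  structure(list(
    person_id = profile$person_id,
    replicate_id = 1L,
    event_years = r$event_cycle[1, ] + 1,
    death_year = r$death_cycle[1] + 1,
    cause_of_death = r$cause_of_death[1],
    life_years = r$ly[1], qalys = r$qaly[1],
    life_years_10y = r$ly10[1], qalys_10y = r$qaly10[1],
    life_years_20y = r$ly20[1], qalys_20y = r$qaly20[1],
    censored_alive = r$state$alive[1],
    audit = if (config$audit)
      data.frame(cycle = seq_along(r$audit) - 1L,
                 exposure = vapply(r$audit, `[[`, 0, "exposure"),
                 utility = vapply(r$audit, `[[`, 0, "utility"))
  ), class = "trajectory")
}

#' Run the microsimulation over a cohort
#'
#' Simulates every individual `config$replicates` times and aggregates:
#' per-person mean (discounted) life years and QALYs at 10-year, 20-year and
#' lifetime horizons, per-endpoint cumulative incidence by year, the
#' cause-of-death distribution, and each person's probability of a first
#' major vascular event within the horizon. Deterministic given
#' `config$master_seed`.
#'
#' @param cohort validated cohort.
#' @param coefset `coefficient_set`.
#' @param config `sim_config`.
#' @param log_mult optional `n x 7` log hazard multipliers (treatment).
#' @return object of class `sim_summary`: `$person` (per-person means),
#'   `$aggregate`, `$incidence` (years x endpoints cumulative incidence over
#'   person-replicates), `$cause_of_death`.
#' @export
run_microsimulation <- function(cohort, coefset, config = sim_config(),
                                log_mult = NULL) {
  if (!nrow(cohort)) cvd_error("cvd_config_error", "empty cohort")
  ctx <- build_sim_context(cohort, coefset, log_mult)
  n <- nrow(cohort)
  R <- config$replicates
  acc <- c("ly", "qaly", "ly10", "qaly10", "ly20", "qaly20")
  sums <- stats::setNames(rep(list(numeric(n)), length(acc)), acc)
  mve_count <- numeric(n)
  max_cycles <- min(config$horizon, AGE_CAP - min(cohort$age_entry))
  inc_counts <- matrix(0, ceiling(max_cycles), length(ENDPOINTS),
                       dimnames = list(NULL, ENDPOINTS))
  cause <- c(vascular = 0, nonvascular = 0, censored = 0)
  for (r in seq_len(R)) {
    res <- engine_run(ctx, config, replicate = r)
    for (a in acc) sums[[a]] <- sums[[a]] + res[[a]]
    mve_count <- mve_count + res$mve
    for (ei in seq_along(ENDPOINTS)) {
      ec <- res$event_cycle[, ei]
      ec <- ec[!is.na(ec)]
      if (length(ec)) {
        tb <- tabulate(ec + 1L, nbins = nrow(inc_counts))
        inc_counts[, ei] <- inc_counts[, ei] + tb
      }
    }
    cod <- res$cause_of_death
    cause["vascular"] <- cause["vascular"] + sum(cod == "vascular")
    cause["nonvascular"] <- cause["nonvascular"] + sum(cod == "nonvascular")
    cause["censored"] <- cause["censored"] + sum(cod == "none")
  }
  person <- data.frame(
    person_id = cohort$person_id,
    life_years = sums$ly / R, qalys = sums$qaly / R,
    life_years_10y = sums$ly10 / R, qalys_10y = sums$qaly10 / R,
    life_years_20y = sums$ly20 / R, qalys_20y = sums$qaly20 / R,
    mve_prob = mve_count / R)
  incidence <- apply(inc_counts, 2, cumsum) / (n * R)
  if (is.null(dim(incidence))) {
    incidence <- matrix(incidence, nrow = 1, dimnames = list(NULL, ENDPOINTS))
  }
  structure(list(
    n = n, replicates = R, config = config,
    person = person,
    aggregate = list(mean_life_years = mean(person$life_years),
                     mean_qalys = mean(person$qalys),
                     mean_life_years_10y = mean(person$life_years_10y),
                     mean_qalys_10y = mean(person$qalys_10y),
                     mean_life_years_20y = mean(person$life_years_20y),
                     mean_qalys_20y = mean(person$qalys_20y)),
    incidence = incidence,
    cause_of_death = cause / (n * R)
  ), class = "sim_summary")
}

#' Cumulative incidence curve from a simulation summary
#' @param summary `sim_summary`.
#' @param endpoint endpoint name.
#' @param years integer years (default: all simulated years).
#' @return named numeric vector: cumulative incidence (proportion of
#'   person-replicates with a first occurrence by each year).
#' @export
incidence_curve <- function(summary, endpoint,
                            years = seq_len(nrow(summary$incidence))) {
  stopifnot(endpoint %in% ENDPOINTS)
  v <- summary$incidence[, endpoint]
  stats::setNames(v[pmin(years, length(v))], years)
}

#' Probabilistic sensitivity analysis over a coefficient-set ensemble
#'
#' Recomputes the cohort summary for every coefficient set in the ensemble;
#' 95% intervals are the empirical 2.5/97.5 percentiles across bootstrap
#' replicates (`replicate_id >= 1`), reported alongside the point estimate
#' (`replicate_id = 0`, or the first set if none is marked).
#'
#' @param cohort validated cohort.
#' @param ensemble list of `coefficient_set`s.
#' @param config `sim_config`.
#' @param metrics aggregate metric names to summarize.
#' @return data frame with point estimate and interval per metric, plus the
#'   full per-set draws in attribute `draws`.
#' @export
run_psa <- function(cohort, ensemble, config = sim_config(),
                    metrics = c("mean_life_years", "mean_qalys")) {
  if (!length(ensemble)) cvd_error("cvd_config_error", "empty ensemble")
  ids <- vapply(ensemble, function(s) s$replicate_id, 0L)
  draws <- t(vapply(ensemble, function(set) {
    s <- run_microsimulation(cohort, set, config)
    unlist(s$aggregate[metrics])
  }, numeric(length(metrics))))
  colnames(draws) <- metrics
  boot <- draws[ids >= 1L, , drop = FALSE]
  point_row <- if (any(ids == 0L)) which(ids == 0L)[1] else 1L
  if (nrow(boot) < 2) {
    warning("fewer than 2 bootstrap replicates: intervals are degenerate")
    if (!nrow(boot)) boot <- draws[point_row, , drop = FALSE]
  }
  out <- data.frame(
    metric = metrics,
    point = draws[point_row, metrics],
    lower = apply(boot, 2, stats::quantile, 0.025, names = FALSE),
    upper = apply(boot, 2, stats::quantile, 0.975, names = FALSE),
    row.names = NULL)
  attr(out, "draws") <- draws
  attr(out, "replicate_ids") <- ids
  out
}
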