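test_that("with zero hazards nothing fires and the age cap does the arithmetic", {
  cs <- flat_model(utility = 1)
  p <- reference_profile(age = 60)
  st <- new_sim_state(p)
  res <- simulate_cycle(p, st, cs)
  expect_false(any(res$fired))
  expect_equal(res$state$current_age, 61)
  tr <- simulate_individual(p, cs, sim_config(master_seed = 4))
  expect_equal(tr$life_years, 50)   # censored alive at 110
  expect_equal(tr$qalys, 50)
  expect_true(tr$censored_alive)
  expect_true(all(is.na(tr$event_years)))
})

test_that("a saturating death hazard kills in the first cycle and aborts later draws", {
  cs <- flat_model(hazards = c(nonvascular_death = 1e9, mi = 1e9))
  p <- reference_profile(age = 60)
  tr <- simulate_individual(p, cs, sim_config(master_seed = 1))
  expect_equal(tr$death_year, 1)
  expect_equal(tr$cause_of_death, "nonvascular")
  expect_equal(tr$life_years, 0.5)  # half-cycle correction in the death year
  # without half-cycle correction the death year contributes nothing
  tr0 <- simulate_individual(p, cs, sim_config(master_seed = 1,
                                               half_cycle_correction = FALSE))
  expect_equal(tr0$life_years, 0)
})

test_that("mean lifetime under a constant death hazard matches the continuous oracle", {
  h <- 0.1  # entry at 40 leaves the age cap essentially non-binding
  cs <- flat_model(hazards = c(nonvascular_death = h))
  co <- generate_cohort(400, seed = 9, config = cohort_config(
    age = c(mean = 40, sd = 1, lo = 40, hi = 40.0001)))
  s <- run_microsimulation(co, cs, sim_config(replicates = 60, master_seed = 3))
  # discrete geometric survival + half cycle: p/(1-p) + 0.5, p = exp(-h)
  p_surv <- exp(-h)
  want <- p_surv / (1 - p_surv) + 0.5
  expect_equal(want, 1 / h, tolerance = 1e-3)  # 1/h to the discretization term
  mean_ly <- s$aggregate$mean_life_years
  se <- 10 / sqrt(400 * 60)  # sd of an exponential(0.1) lifetime is 10
  expect_lt(abs(mean_ly - want), 2.5 * se)
})

test_that("runs are bitwise reproducible and twins are exchangeable", {
  cs <- synthetic_true_model()
  co <- generate_cohort(20, seed = 15)
  cfg <- sim_config(replicates = 3, master_seed = 11)
  s1 <- run_microsimulation(co, cs, cfg)
  s2 <- run_microsimulation(co, cs, cfg)
  expect_identical(s1$person, s2$person)
  expect_identical(s1$incidence, s2$incidence)
  # identical twin profiles get equal expected outputs within MC error
  twin <- co[rep(1, 2), ]; twin$person_id <- c("a", "b")
  class(twin) <- class(co)
  st <- run_microsimulation(twin, cs, sim_config(replicates = 400,
                                                 master_seed = 2))
  expect_lt(abs(diff(st$person$life_years)),
            3 * sqrt(2) * 12 / sqrt(400))
})

test_that("every completed trajectory has exactly one death cause or cap censoring", {
  cs <- synthetic_true_model()
  co <- generate_cohort(60, seed = 77,
                        config = cohort_config(p_cvd = 0.3))
  for (i in seq_len(20)) {
    p <- co[i, , drop = FALSE]; class(p) <- class(co)
    tr <- simulate_individual(p, cs, sim_config(master_seed = i, audit = TRUE))
    if (tr$censored_alive) {
      expect_true(is.na(tr$death_year))
      expect_equal(tr$cause_of_death, "none")
    } else {
      expect_true(tr$cause_of_death %in% c("vascular", "nonvascular"))
      expect_false(is.na(tr$death_year))
    }
    # accounting identity: life years and QALYs reproducible from the audit
    expect_equal(tr$life_years, sum(tr$audit$exposure), tolerance = 1e-12)
    expect_equal(tr$qalys, sum(tr$audit$exposure * tr$audit$utility),
                 tolerance = 1e-12)
    # utility stream respects the EQ-5D bounds, so QALYs are bracketed
    expect_true(all(tr$audit$utility >= -0.594 & tr$audit$utility <= 1))
    expect_lte(tr$qalys, tr$life_years + 1e-12)
    expect_gte(tr$qalys, -0.594 * tr$life_years - 1e-12)
  }
})

test_that("a huge post-MI effect on vascular death kills soon after MI", {
  cs <- flat_model(hazards = c(mi = 0.08, vascular_death = 1e-4,
                               nonvascular_death = 1e-4),
                   coefs = list(vascular_death = c(mi_this_year = 12,
                                                   mi_prior_years = 12)))
  co <- generate_cohort(150, seed = 33)
  s <- run_microsimulation(co, cs, sim_config(replicates = 2, master_seed = 6))
  # survival after MI is short: nearly everyone with an MI dies of vascular
  # causes, and the MI and vascular-death incidence curves track closely
  mi_ci <- incidence_curve(s, "mi")
  vd_ci <- incidence_curve(s, "vascular_death")
  lag <- vd_ci[-(1:2)] - mi_ci[seq_len(length(mi_ci) - 2)]
  expect_true(all(lag > -0.02))  # vascular death within ~2 years of MI
  expect_gt(s$cause_of_death[["vascular"]], 0.9 * max(mi_ci))
})

test_that("doubling replicates shrinks the Monte Carlo SE roughly by sqrt(2)", {
  cs <- flat_model(hazards = c(nonvascular_death = 0.08))
  co <- generate_cohort(30, seed = 2)
  mean_ly <- function(R, seed)
    run_microsimulation(co, cs, sim_config(replicates = R, master_seed = seed)
                        )$aggregate$mean_life_years
  m1 <- vapply(1:12, function(s) mean_ly(4, 1000 + s), 0)
  m2 <- vapply(1:12, function(s) mean_ly(8, 2000 + s), 0)
  ratio <- sd(m1) / sd(m2)
  expect_gt(ratio, 1.0)
  expect_lt(ratio, 2.1)
})

test_that("event ordering is fair when hazards are small", {
  # with all annual hazards <= 0.05 the per-endpoint incidence should not
  # depend on where in the cycle an endpoint is drawn
  cs <- flat_model(hazards = c(mi = 0.05, cancer = 0.05,
                               nonvascular_death = 0.05))
  co <- generate_cohort(2000, seed = 12)
  s <- run_microsimulation(co, cs, sim_config(replicates = 1, master_seed = 8,
                                              horizon = 5))
  ci_mi <- incidence_curve(s, "mi", 1:5)
  ci_ca <- incidence_curve(s, "cancer", 1:5)
  se <- sqrt(2 * 0.2 * 0.8 / 2000)
  expect_lt(abs(ci_mi[[5]] - ci_ca[[5]]), 3 * se)
})

test_that("PSA intervals behave: degenerate, jitter-monotone, and contain the point", {
  base <- flat_model(hazards = c(nonvascular_death = 0.05, mi = 0.01))
  co <- generate_cohort(25, seed = 19)
  cfg <- sim_config(replicates = 2, master_seed = 5, horizon = 30)
  same <- lapply(0:3, function(k) { b <- base; b$replicate_id <- k; b })
  res0 <- run_psa(co, same, cfg)
  expect_equal(res0$lower, res0$upper, tolerance = 1e-12)
  expect_warning(run_psa(co, same[1:2], cfg), "degenerate")
  width <- vapply(c(0.05, 0.15, 0.4), function(sdj) {
    set.seed(40)
    ens <- lapply(0:10, function(k) {
      b <- base; b$replicate_id <- k
      if (k > 0) {
        key <- "nonvascular_death.no_cvd"
        b$equations[[key]]$baseline$log_hazard_intercept <-
          b$equations[[key]]$baseline$log_hazard_intercept + rnorm(1, 0, sdj)
      }
      b
    })
    r <- run_psa(co, ens, cfg)
    r$upper[1] - r$lower[1]
  }, 0)
  expect_true(all(diff(width) > 0))
})
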