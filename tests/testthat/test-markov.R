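test_that("conditional transition probability follows the survival curve", {
  expo <- surv_spec("exponential", rate = 0.05)
  dt <- cycle_length_months
  # memorylessness: independent of t
  p1 <- conditional_transition_prob(expo, 0, dt)
  p2 <- conditional_transition_prob(expo, 37.3, dt)
  expect_equal(p1, 1 - exp(-0.05 * dt), tolerance = 1e-12)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(conditional_transition_prob(expo, 12, 0), 0)
  wb <- surv_spec("weibull", shape = 1.232, scale = 70.275)
  expect_equal(conditional_transition_prob(wb, 12, 0.690),
               1 - psurv(wb, 12.690) / psurv(wb, 12), tolerance = 1e-12)
})

test_that("transition matrices are stochastic over the whole horizon", {
  cfg <- engine_config(base_pt, base_specs)
  expect_equal(cfg$horizon_cycles, 174)
  for (arm in cfg$arms) {
    for (cc in seq_len(cfg$horizon_cycles)) {
      M <- build_transition_matrix(cc, cfg, arm, adj_exit_frac = 0.1)
      expect_true(all(abs(rowSums(M) - 1) < 1e-10))
      expect_true(all(M >= 0 & M <= 1))
      if (cc < 5 || cc > 6)
        expect_equal(M["NEOADJ", "POST_SURG_RT"], 0)
      if (arm == "placebo" || cc < 6 || cc > 10)
        expect_equal(M["POST_SURG_RT", "ADJUVANT"], 0)
    }
  }
})

test_that("window gating and the no-event limit behave as designed", {
  # survival stuck at 1: only the windowed flows and operative deaths move mass
  flat <- list(os = surv_spec("exponential", rate = 1e-12),
               efs = surv_spec("exponential", rate = 1e-12))
  cfg <- engine_config(base_pt, list(pembrolizumab = flat, placebo = flat),
                       bg_mortality = FALSE)
  M3 <- build_transition_matrix(3, cfg, "pembrolizumab")
  expect_equal(M3["NEOADJ", "NEOADJ"], 1, tolerance = 1e-10)
  M5 <- build_transition_matrix(5, cfg, "pembrolizumab")
  expect_gt(M5["NEOADJ", "POST_SURG_RT"], 0)
  expect_equal(M5["NEOADJ", "NEOADJ"] + M5["NEOADJ", "POST_SURG_RT"] +
                 M5["NEOADJ", "DEATH"], 1, tolerance = 1e-12)
  tr <- run_cohort(cfg, "pembrolizumab")
  # cumulative local-therapy uptake matches the configured proportion
  expect_equal(sum(tr$entrants[, "local"]),
               unname(pt_value(base_pt, "prop_local_therapy_pem")),
               tolerance = 1e-6)
  # adjuvant uptake applies to local-therapy patients who survive surgery;
  # movers arriving at the end of surgery-window cycle 6 only see 4 of the
  # 5 adjuvant-window cycles, so their cumulative uptake is one factor short
  qs <- 1 - sqrt(1 - pt_value(base_pt, "prop_local_therapy_pem"))
  qa <- 1 - (1 - pt_value(base_pt, "prop_adjuvant_uptake"))^(1 / 5)
  surv_op <- 1 - pt_value(base_pt, "prop_surgery_among_local") *
    pt_value(base_pt, "p_surgery_mortality_30d")
  expected_adj <- surv_op * (qs * (1 - (1 - qa)^5) +
                               (1 - qs) * qs * (1 - (1 - qa)^4))
  expect_equal(sum(tr$entrants[, "adjuvant"]), unname(expected_adj),
               tolerance = 1e-6)
})

test_that("cohort trace conserves probability and is internally consistent", {
  for (arm in c("pembrolizumab", "placebo")) {
    tr <- run_cohort(engine_config(base_pt, base_specs), arm)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
    expect_true(all(tr$occupancy >= -1e-12 & tr$occupancy <= 1 + 1e-12))
    expect_true(all(diff(tr$occupancy[, "DEATH"]) >= -1e-12))
    expect_equal(tr$occupancy[1, ], c(NEOADJ = 1, POST_SURG_RT = 0,
                                      ADJUVANT = 0, PD = 0, DEATH = 0))
    # death entrants sum to final death occupancy
    expect_equal(sum(tr$entrants[, "death"]),
                 unname(tr$occupancy[175, "DEATH"]), tolerance = 1e-10)
  }
})

test_that("cohort survival reproduces the fitted OS curve when floors are off", {
  pt0 <- pt_set(base_pt, c(p_surgery_mortality_30d = 0))
  cfg <- engine_config(pt0, base_specs, bg_mortality = FALSE)
  for (arm in cfg$arms) {
    tr <- run_cohort(cfg, arm)
    alive <- 1 - tr$occupancy[, "DEATH"]
    expected <- psurv(cfg$surv_specs[[arm]]$os,
                      (0:cfg$horizon_cycles) * cycle_length_months)
    expect_lt(max(abs(alive - expected)), 1e-6)
  }
})

test_that("progression incidence dominance holds under EFS dominance", {
  cfg <- engine_config(base_pt, base_specs)
  tt <- (1:174) * cycle_length_months
  # base-case pembrolizumab EFS dominates the comparator's (up to a
  # sub-1e-4 dip of the heavy-tailed generalized gamma near t = 1.4 months)
  expect_true(all(psurv(base_specs$pembrolizumab$efs, tt) >=
                    psurv(base_specs$placebo$efs, tt) - 2.5e-4))
  # cumulative entries into PD can never exceed the comparator's; note the
  # PD *occupancy* itself crosses late in the horizon because the
  # intervention also keeps progressed patients alive longer
  in_pem <- cumsum(run_cohort(cfg, "pembrolizumab")$entrants[, "pd"])
  in_pla <- cumsum(run_cohort(cfg, "placebo")$entrants[, "pd"])
  expect_true(all(in_pem <= in_pla + 1e-9))
})

test_that("EFS identical to OS with closed windows leaves PD empty", {
  sp <- list(os = surv_spec("weibull", shape = 1.232, scale = 70.275),
             efs = surv_spec("weibull", shape = 1.232, scale = 70.275))
  pt0 <- pt_set(base_pt, c(prop_local_therapy_pem = 0,
                           prop_local_therapy_placebo = 0))
  cfg <- engine_config(pt0, list(pembrolizumab = sp, placebo = sp),
                       bg_mortality = FALSE)
  tr <- run_cohort(cfg, "placebo")
  expect_true(all(tr$occupancy[, "PD"] == 0))
})

test_that("micro-simulation walkers agree with the deterministic trace", {
  cfg <- engine_config(base_pt, base_specs)
  n <- 1e6
  for (arm in cfg$arms) {
    tr <- run_cohort(cfg, arm)
    ms <- microsim_occupancy(cfg, arm, n_walkers = n, seed = 5)
    se <- sqrt(pmax(tr$occupancy * (1 - tr$occupancy), 1e-12) / n)
    z <- abs(tr$occupancy - ms) / pmax(se, 1e-9)
    # 875 correlated entries: individual z-scores sit within 3 s.e. for
    # all but a Monte-Carlo handful; the familywise max stays below 5
    expect_gt(mean(z <= 3), 0.95)
    expect_true(all(abs(tr$occupancy - ms) <= 5 * se + 1e-5), info = arm)
  }
})

test_that("adjuvant residency is limited to the configured administrations", {
  # with no progression or death, adjuvant occupancy must empty exactly
  # adjuvant_max_cycles after the entry window closes
  flat <- list(os = surv_spec("exponential", rate = 1e-12),
               efs = surv_spec("exponential", rate = 1e-12))
  cfg <- engine_config(base_pt, list(pembrolizumab = flat, placebo = flat),
                       bg_mortality = FALSE)
  tr <- run_cohort(cfg, "pembrolizumab")
  last_entry <- cfg$window_surg_to_adj[2]
  expect_gt(tr$occupancy[last_entry + 1, "ADJUVANT"], 0)
  expect_equal(unname(tr$occupancy[last_entry + cfg$adjuvant_max_cycles + 2,
                                   "ADJUVANT"]), 0, tolerance = 1e-12)
})
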