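test_that("discount factors follow the annual rate at cycle granularity", {
  expect_equal(per_cycle_discount(0.03, 0), 1)
  expect_equal(per_cycle_discount(0, 0:50), rep(1, 51))
  # about one year of 21-day cycles
  expect_equal(per_cycle_discount(0.03, 365.25 / 21), 1 / 1.03,
               tolerance = 1e-12)
  expect_error(per_cycle_discount(-0.01, 1))
})

test_that("drug administration costs reproduce the unit arithmetic", {
  res <- get_base_res()
  tr <- run_cohort(engine_config(base_pt, base_specs), "pembrolizumab")
  # pembrolizumab: 200 mg x 54.81 USD/mg per administration
  pem_admin <- 200 * 54.81
  expect_equal(pem_admin, 10962)
  disc <- per_cycle_discount(0.03, seq_len(174))
  expected_pem <- sum((tr$drug_occ[, "neoadj"] + tr$drug_occ[, "adj"]) *
                        pem_admin * disc)
  expect_equal(res$intervention$breakdown[["drug_pembrolizumab"]],
               expected_pem, tolerance = 1e-9)
  # cisplatin per administration: 75 mg/m2 x 1.86 m2 x 0.32 USD/mg
  expect_equal(75 * 1.86 * 0.32, 44.64)
  # placebo arm carries no checkpoint-inhibitor cost
  expect_equal(res$comparator$breakdown[["drug_pembrolizumab"]], 0)
})

test_that("QALY accrual integrates occupancy-weighted utilities", {
  # immortal, event-free cohort at utility 1: QALYs = horizon in years
  flat <- list(os = surv_spec("exponential", rate = 1e-12),
               efs = surv_spec("exponential", rate = 1e-12))
  pt0 <- pt_set(base_pt, c(utility_pf = 1, utility_surgery = 1,
                           utility_radiotherapy = 1, utility_pd = 1,
                           risk_anemia_pem = 0, risk_neutropenia_pem = 0,
                           risk_thrombocytopenia_pem = 0,
                           p_surgery_mortality_30d = 0,
                           discount_rate = 0))
  cfg <- engine_config(pt0, list(pembrolizumab = flat, placebo = flat),
                       bg_mortality = FALSE)
  ar <- accrue(run_cohort(cfg, "pembrolizumab"))
  expect_equal(ar$total_qaly, 174 * 21 / 365.25, tolerance = 1e-9)
  expect_equal(ar$total_qaly, 10.004, tolerance = 1e-3)
})

test_that("discounting lowers both cost and QALY totals", {
  r0 <- run_cea_q(pt_set(base_pt, c(discount_rate = 0)))
  r8 <- run_cea_q(pt_set(base_pt, c(discount_rate = 0.08)))
  expect_lt(r8$intervention$total_cost, r0$intervention$total_cost)
  expect_lt(r8$intervention$total_qaly, r0$intervention$total_qaly)
  expect_lt(r8$comparator$total_cost, r0$comparator$total_cost)
  # discounted never exceeds undiscounted within one run
  res <- get_base_res()
  expect_lte(res$intervention$total_cost, res$intervention$undiscounted_cost)
  expect_lte(res$intervention$total_qaly, res$intervention$undiscounted_qaly)
})

test_that("cost ledger categories sum to the total", {
  res <- get_base_res()
  for (a in list(res$intervention, res$comparator))
    expect_equal(sum(a$breakdown), a$total_cost, tolerance = 1e-6)
})

test_that("incremental statistics reproduce the published arithmetic", {
  mk <- function(cost, qaly, arm)
    structure(list(arm = arm, total_cost = cost, total_qaly = qaly),
              class = "arm_result")
  # ICER and NMB from the printed incremental cost and full-precision QALY
  cmp <- compare(mk(114752.8, 1.217894, "a"), mk(0, 0, "b"), wtp = 150000)
  expect_equal(cmp$icer, 94222.29, tolerance = 1e-6)
  expect_equal(cmp$nmb, 67931.3, tolerance = 1e-4)
  ident <- compare(mk(100, 1, "a"), mk(100, 1, "b"))
  expect_equal(ident$delta_cost, 0)
  expect_equal(ident$nmb, 0)
  expect_true(is.na(ident$icer))
  dom <- compare(mk(90, 2, "a"), mk(100, 1, "b"))
  expect_equal(dom$dominance, "dominant")
  expect_equal(compare(mk(110, 0.5, "a"), mk(100, 1, "b"))$dominance,
               "dominated")
})

test_that("NMB is positive exactly when the ICER undercuts the threshold", {
  res <- get_base_res()
  expect_true(res$delta_qaly > 0)
  expect_equal(res$nmb > 0, res$icer < res$wtp)
  # sweep thresholds around the ICER
  for (l in c(5e4, 9e4, 1e5, 1.5e5, 2.5e5)) {
    r <- compare(res$intervention, res$comparator, wtp = l)
    expect_equal(r$nmb > 0, r$icer < l)
  }
})

test_that("scaling every cost scales incremental cost and ICER exactly", {
  k <- 1.7
  df <- as.data.frame(base_pt)
  cost_names <- df$name[grepl("^cost_", df$name)]
  ptk <- pt_set(base_pt, stats::setNames(pt_value(base_pt, cost_names) * k,
                                         cost_names))
  r1 <- get_base_res()
  rk <- run_cea_q(ptk)
  expect_equal(rk$delta_cost, k * r1$delta_cost, tolerance = 1e-9)
  expect_equal(rk$icer, k * r1$icer, tolerance = 1e-9)
  expect_equal(rk$delta_qaly, r1$delta_qaly, tolerance = 1e-12)
})
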