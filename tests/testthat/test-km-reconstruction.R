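test_that("KM estimator matches hand calculations and edge cases", {
  km <- km_estimator(ipd_sample(c(1, 2), c(1, 1)))
  expect_equal(km_at(km, c(0.5, 1, 1.5, 2, 3)), c(1, 0.5, 0.5, 0, 0))
  kmc <- km_estimator(ipd_sample(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(kmc$surv == 1))
})

test_that("KM estimate converges to the true survival curve", {
  set.seed(11)
  sp <- surv_spec("exponential", rate = 0.05)
  ipd <- generate_ipd(sp, 1000)
  km <- km_estimator(ipd)
  tt <- seq(0.5, stats::quantile(ipd$time, 0.98), length.out = 200)
  expect_lt(max(abs(km_at(km, tt) - psurv(sp, tt))), 0.05)
})

test_that("digitization with zero jitter lies exactly on the KM steps", {
  set.seed(21)
  ipd <- generate_ipd(surv_spec("weibull", shape = 1.3, scale = 30), 200,
                      censor_admin = 48)
  dc <- digitize(ipd, n_points = 30, risk_interval = 6, jitter_sd = 0)
  km <- km_estimator(ipd)
  expect_equal(dc$points$survival, km_at(km, dc$points$time),
               tolerance = 1e-12)
  expect_equal(dc$risk_table$n_risk[1], 200L)
})

test_that("digitized coordinates stay monotone for any jitter level", {
  set.seed(31)
  ipd <- generate_ipd(surv_spec("lognormal", meanlog = 3, sdlog = 1), 150,
                      censor_admin = 60)
  for (s in 1:100) {
    dc <- digitize(ipd, n_points = 20, risk_interval = 12,
                   jitter_sd = 0.03, seed = s)
    expect_true(all(diff(dc$points$survival) <= 0))
    expect_true(all(dc$points$survival >= 0 & dc$points$survival <= 1))
  }
})

test_that("reconstruction is lossless for a fully observed step function", {
  ev <- ipd_sample(1:10, rep(1, 10))
  km <- km_estimator(ev)
  dc <- digitized_curve(data.frame(time = km$time, survival = km$surv),
                        data.frame(time = c(0, 5, 10),
                                   n_risk = c(10, 6, 1)))
  rec <- reconstruct_ipd(dc)
  expect_equal(sort(rec$time), as.numeric(1:10))
  expect_equal(rec$event, rep(1L, 10))
})

test_that("digitize -> reconstruct round trip tracks the input curve", {
  set.seed(42)
  ipd <- generate_ipd(surv_spec("weibull", shape = 1.232, scale = 70.275),
                      400, censor_admin = 48, censor_rate = 0.008)
  dc <- digitize(ipd, n_points = 40, risk_interval = 6)
  rec <- reconstruct_ipd(dc)
  km_out <- km_estimator(rec)
  dev <- abs(km_at(km_out, dc$points$time) - dc$points$survival)
  expect_lt(max(dev), 0.02)
  # conservation: every pseudo patient is accounted for
  expect_equal(nrow(rec), 400)
  expect_equal(sum(rec$event), sum(ipd$event))
  # monotonicity of the reconstructed curve
  expect_true(all(diff(km_out$surv) <= 0))
})

test_that("per-interval bookkeeping conserves the risk set", {
  set.seed(52)
  ipd <- generate_ipd(surv_spec("gengamma", mu = 2.677, sigma = 1.316,
                                Q = -0.498), 300, censor_admin = 42,
                      censor_rate = 0.01)
  dc <- digitize(ipd, n_points = 35, risk_interval = 6)
  rec <- reconstruct_ipd(dc)
  # implied at-risk at each risk-table time equals the published number
  for (j in seq_len(nrow(dc$risk_table))) {
    implied <- sum(rec$time >= dc$risk_table$time[j] - 1e-9)
    expect_equal(implied, dc$risk_table$n_risk[j],
                 info = paste("risk time", dc$risk_table$time[j]))
  }
})

test_that("reconstructed data refit within the bootstrap band of a direct fit", {
  set.seed(62)
  truth <- surv_spec("weibull", shape = 1.232, scale = 70.275)
  ipd <- generate_ipd(truth, 400, censor_admin = 48, censor_rate = 0.008)
  direct <- fit_parametric(ipd, "weibull")
  rec <- reconstruct_ipd(digitize(ipd, n_points = 40, risk_interval = 6))
  refit <- fit_parametric(rec, "weibull")
  B <- 100
  boot <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(ipd), replace = TRUE)
    bf <- tryCatch(
      fit_parametric(ipd_sample(ipd$time[idx], ipd$event[idx]), "weibull"),
      error = function(e) NULL)
    if (!is.null(bf)) boot[b, ] <- coef(bf)
  }
  ci <- apply(boot, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
  expect_gte(coef(refit)["shape"], ci[1, 1])
  expect_lte(coef(refit)["shape"], ci[2, 1])
  expect_gte(coef(refit)["scale"], ci[1, 2])
  expect_lte(coef(refit)["scale"], ci[2, 2])
})

test_that("invalid digitized inputs are rejected", {
  pts <- data.frame(time = c(0, 1, 2), survival = c(1, 0.8, 0.9))
  rt <- data.frame(time = c(0, 2), n_risk = c(10, 5))
  expect_error(digitized_curve(pts, rt), "nonincreasing")
  expect_error(digitized_curve(data.frame(time = c(0, 1), survival = c(1, 0.8)),
                               data.frame(time = 0, n_risk = 10)),
               "at least 2")
})
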