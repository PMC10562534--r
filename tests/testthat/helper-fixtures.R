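# Shared fixtures: built once per test run, all generated in code.

base_pt <- table1_fixture()
base_specs <- base_survival_specs()

# run_cea without re-reading the packaged JSON/CSV on every call
run_cea_q <- function(pt = base_pt, ...) run_cea(pt, base_specs, ...)

.base_res_cache <- new.env(parent = emptyenv())
get_base_res <- function() {
  if (is.null(.base_res_cache$res)) .base_res_cache$res <- run_cea_q()
  .base_res_cache$res
}

# the four base-case survival specs plus representatives of the remaining
# families, for property sweeps
all_family_specs <- list(
  surv_spec("exponential", rate = 0.05),
  surv_spec("weibull", shape = 1.232, scale = 70.275),
  surv_spec("loglogistic", shape = 1.6, scale = 24),
  surv_spec("lognormal", meanlog = 5.023, sdlog = 2.074),
  surv_spec("gengamma", mu = 2.866, sigma = 1.951, Q = -1.399),
  surv_spec("gengamma", mu = 2.677, sigma = 1.316, Q = -0.498),
  surv_spec("gamma", shape = 1.4, rate = 0.03),
  surv_spec("gompertz", shape = 0.04, rate = 0.012),
  surv_spec("gompertz", shape = -0.02, rate = 0.03)
)

# direct censored log-likelihood used as an independent probe of fits
loglik_probe <- function(spec, ipd) {
  sum(dsurv(spec, ipd$time[ipd$event == 1], log = TRUE)) +
    sum(log(psurv(spec, ipd$time[ipd$event == 0])))
}
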