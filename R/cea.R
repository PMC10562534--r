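#' Run the full base-case cost-effectiveness analysis
#'
#' Convenience wrapper: builds the engine configuration, runs the cohort
#' model for both strategies, accrues discounted costs and QALYs and
#' returns the incremental comparison.
#'
#' @param pt parameter table (default: packaged base case).
#' @param surv_specs per-arm survival specs (default: packaged fitted
#'   models).
#' @param horizon_years analytic horizon.
#' @param wtp willingness-to-pay threshold (USD/QALY).
#' @param ... further arguments to \code{\link{engine_config}}.
#' @return a \code{\link{compare}} result (class \code{"ce_result"}) whose
#'   \code{$intervention}/\code{$comparator} hold the per-arm accruals.
#' @examples
#' \donttest{
#' res <- run_cea()
#' print(res)
#' }
#' @export
run_cea <- function(pt = table1_fixture(), surv_specs = base_survival_specs(),
                    horizon_years = 10, wtp = 150000, ...) {
  cfg <- engine_config(pt, surv_specs, horizon_years = horizon_years, ...)
  arms <- lapply(cfg$arms, function(a) accrue(run_cohort(cfg, a)))
  names(arms) <- cfg$arms
  compare(arms[[1]], arms[[2]], wtp = wtp)
}
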