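#' Individual patient data sample
#'
#' Container for right-censored time-to-event records: positive finite times
#' (months) and an event indicator (1 observed, 0 censored).
#'
#' @param time positive event/censoring times in months.
#' @param event 0/1 indicator, 1 = observed event.
#' @return object of class \code{"ipd_sample"}, a data.frame with columns
#'   \code{time}, \code{event}.
#' @export
ipd_sample <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite")
  if (!all(event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (observed)")
  structure(data.frame(time = as.numeric(time), event = as.integer(event)),
            class = c("ipd_sample", "data.frame"))
}

#' @export
print.ipd_sample <- function(x, ...) {
  cat(sprintf("<ipd_sample> n=%d, events=%d, censored=%d, follow-up %.2f-%.2f months\n",
              nrow(x), sum(x$event), sum(1 - x$event), min(x$time), max(x$time)))
  invisible(x)
}

#' Read / write IPD as two-column CSV (time, event)
#' @param path file path.
#' @return \code{read_ipd}: an \code{ipd_sample}.
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "event") %in% names(d)))
    stop("IPD CSV must have columns time, event")
  ipd_sample(d$time, d$event)
}

#' @rdname read_ipd
#' @param ipd an \code{ipd_sample}.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(as.data.frame(ipd)[c("time", "event")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Generate synthetic right-censored survival data
#'
#' Draws event times from a parametric survival spec by inverse transform
#' and applies administrative and/or random-exponential censoring,
#' emulating trial follow-up.  This is the ground-truth generator used to
#' exercise the Kaplan-Meier digitization / reconstruction / refitting
#' pipeline without any external data.
#'
#' @param spec a \code{\link{surv_spec}} (truth).
#' @param n sample size.
#' @param censor_admin administrative censoring time in months
#'   (\code{Inf} = none).  Event times beyond it (including infinite times
#'   from plateauing families) are censored there.
#' @param censor_rate rate (per month) of an independent exponential
#'   censoring process (0 = none).
#' @param seed optional integer seed (local RNG, does not disturb the
#'   global stream when supplied).
#' @return an \code{\link{ipd_sample}}.
#' @export
generate_ipd <- function(spec, n, censor_admin = Inf, censor_rate = 0,
                         seed = NULL) {
  stopifnot(n >= 1)
  if (censor_admin <= 0)
    stop("administrative censoring at time <= 0 would censor every record at entry")
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  tev <- rsurv(n, spec)
  tcen <- rep(censor_admin, n)
  if (censor_rate > 0)
    tcen <- pmin(tcen, stats::rexp(n, censor_rate))
  time <- pmin(tev, tcen)
  event <- as.integer(tev <= tcen)
  if (any(!is.finite(time)))
    stop("infinite times generated without administrative censoring; ",
         "set censor_admin for plateauing families")
  ipd_sample(time, event)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
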