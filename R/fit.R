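#' Censored maximum-likelihood fitting of parametric survival models
#'
#' Maximizes the right-censored log-likelihood
#' \deqn{\ell = \sum_i [d_i \log f(t_i) + (1-d_i) \log S(t_i)]}
#' for one of the seven supported families.  Positive parameters are
#' optimized on the log scale (Q of the generalized gamma and the Gompertz
#' shape stay unconstrained); because generalized-gamma likelihoods can be
#' multimodal, optimization restarts from a fixed set of heuristic,
#' data-driven initial points and keeps the best optimum, which makes the
#' fit deterministic for a given sample.
#'
#' @param ipd an \code{\link{ipd_sample}} with at least 10 records and at
#'   least one observed event.
#' @param family family name, see \code{\link{surv_spec}}.
#' @param reltol convergence tolerance on the log-likelihood.
#' @return object of class \code{"parsurv_fit"}: list with \code{spec},
#'   \code{loglik}, \code{aic}, \code{bic}, \code{n}, \code{k},
#'   \code{converged}.
#' @examples
#' set.seed(1)
#' ipd <- generate_ipd(surv_spec("exponential", rate = 0.05), 500)
#' fit_parametric(ipd, "exponential")
#' @export
fit_parametric <- function(ipd, family, reltol = 1e-10) {
  stopifnot(inherits(ipd, "ipd_sample"))
  family <- match.arg(family, names(.surv_families))
  if (nrow(ipd) < 10) stop("need at least 10 records to fit")
  if (sum(ipd$event) < 1) stop("degenerate data: all records censored")
  t <- ipd$time; d <- ipd$event

  nll <- function(theta) {
    sp <- .theta_to_spec(theta, family)
    if (is.null(sp)) return(1e10)
    ll <- sum(dsurv(sp, t[d == 1], log = TRUE)) +
      sum(log(pmax(psurv(sp, t[d == 0]), 1e-300)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  best <- NULL
  for (theta0 in .fit_starts(t, d, family)) {
    opt <- tryCatch(
      if (length(theta0) == 1)
        stats::optim(theta0, nll, method = "Brent", lower = theta0 - 15,
                     upper = theta0 + 15)
      else
        stats::optim(theta0, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    opt <- tryCatch(
      stats::optim(opt$par, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = reltol)),
      error = function(e) opt)
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best)) stop("optimization failed for family ", family)
  spec <- .theta_to_spec(best$par, family)
  ll <- -best$value
  k <- length(best$par)
  n <- nrow(ipd)
  structure(list(spec = spec, loglik = ll, aic = 2 * k - 2 * ll,
                 bic = k * log(n) - 2 * ll, n = n, k = k,
                 converged = best$convergence == 0),
            class = "parsurv_fit")
}

# unconstrained parameter vector -> surv_spec (NULL if invalid)
.theta_to_spec <- function(theta, family) {
  p <- switch(family,
    exponential = c(rate = exp(theta[1])),
    weibull     = c(shape = exp(theta[1]), scale = exp(theta[2])),
    loglogistic = c(shape = exp(theta[1]), scale = exp(theta[2])),
    lognormal   = c(meanlog = theta[1], sdlog = exp(theta[2])),
    gengamma    = c(mu = theta[1], sigma = exp(theta[2]), Q = theta[3]),
    gamma       = c(shape = exp(theta[1]), rate = exp(theta[2])),
    gompertz    = c(shape = theta[1], rate = exp(theta[2]))
  )
  if (any(!is.finite(p)) || any(abs(p) > 1e8)) return(NULL)
  tryCatch(do.call(surv_spec, c(list(family), as.list(p))),
           error = function(e) NULL)
}

# Fixed multi-start policy: method-of-moments style anchors from the data
# plus spread-out perturbations.  Same sample -> same starts.
.fit_starts <- function(t, d, family) {
  mrate <- sum(d) / sum(t)                   # exponential MLE
  mlog <- mean(log(t)); slog <- max(stats::sd(log(t)), 0.1)
  base <- switch(family,
    exponential = list(log(mrate)),
    weibull     = list(c(0, log(1 / mrate)), c(log(1.5), log(1 / mrate)),
                       c(log(0.7), log(1 / mrate))),
    loglogistic = list(c(0, mlog), c(log(2), mlog), c(log(0.7), mlog)),
    lognormal   = list(c(mlog, log(slog))),
    gengamma    = list(c(mlog, log(slog), 0.01), c(mlog, log(slog), 1),
                       c(mlog, log(slog), -1), c(mlog, log(slog), 2),
                       c(mlog, log(slog), -2)),
    gamma       = list(c(0, log(mrate)), c(log(2), log(2 * mrate)),
                       c(log(0.5), log(0.5 * mrate))),
    gompertz    = list(c(0.001, log(mrate)), c(0.02, log(mrate / 2)),
                       c(-0.02, log(mrate)))
  )
  base
}

#' @export
print.parsurv_fit <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  logLik %.3f on %d param(s), n=%d | AIC %.2f  BIC %.2f%s\n",
              x$loglik, x$k, x$n, x$aic, x$bic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.parsurv_fit <- function(object, ...) object$spec$params

#' @export
logLik.parsurv_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Rank competing survival fits by information criteria
#'
#' Orders fits by AIC ascending, breaking ties by BIC and then by fewer
#' parameters, the selection rule used to pick the extrapolation family
#' for each arm and endpoint.
#'
#' @param fits a (optionally named) list of \code{parsurv_fit} objects on
#'   the same sample.
#' @return the list reordered best-first, with attribute \code{"ranking"}
#'   (a data.frame of family, k, loglik, aic, bic).
#' @export
select_best <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied")
  stopifnot(all(vapply(fits, inherits, TRUE, "parsurv_fit")))
  ns <- unique(vapply(fits, function(f) f$n, 0))
  if (length(ns) != 1) stop("fits are not on the same sample")
  tab <- data.frame(
    family = vapply(fits, function(f) f$spec$family, ""),
    k = vapply(fits, function(f) f$k, 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    bic = vapply(fits, function(f) f$bic, 0))
  ord <- order(tab$aic, tab$bic, tab$k)
  out <- fits[ord]
  attr(out, "ranking") <- tab[ord, , drop = FALSE]
  out
}

#' Fit all seven families and rank them
#'
#' @inheritParams fit_parametric
#' @param families subset of families to fit.
#' @return ranked list as from \code{\link{select_best}}.
#' @export
fit_all_families <- function(ipd, families = names(.surv_families)) {
  fits <- lapply(families, function(f)
    tryCatch(fit_parametric(ipd, f), error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, TRUE)]
  select_best(fits)
}
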