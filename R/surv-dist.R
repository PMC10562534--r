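#' Parametric survival model specification
#'
#' Construct a validated specification of a parametric survival family with
#' its parameter vector.  Seven families are supported, the set routinely
#' used for extrapolating oncology trial endpoints: exponential, Weibull,
#' log-logistic, log-normal, generalized gamma, gamma and Gompertz.  Times
#' are in months throughout.
#'
#' The generalized gamma uses the Prentice \code{(mu, sigma, Q)}
#' parameterization: \code{Q -> 0} recovers the log-normal with
#' \code{meanlog = mu, sdlog = sigma}, and \code{Q = 1} recovers the Weibull
#' with \code{shape = 1/sigma, scale = exp(mu)}.  \code{Q < 0} is permitted.
#' The Gompertz uses (shape, rate) with hazard \code{rate * exp(shape * t)};
#' negative shape gives a survival plateau \code{exp(-rate/|shape|)}.
#'
#' @param family one of \code{"exponential"}, \code{"weibull"},
#'   \code{"loglogistic"}, \code{"lognormal"}, \code{"gengamma"},
#'   \code{"gamma"}, \code{"gompertz"}.
#' @param ... named parameters for the family (see Details).
#' @return an object of class \code{"surv_spec"}.
#' @examples
#' sp <- surv_spec("weibull", shape = 1.232, scale = 70.275)
#' psurv(sp, c(0, 12, 70.275))
#' @export
surv_spec <- function(family, ...) {
  family <- match.arg(family, names(.surv_families))
  params <- unlist(list(...))
  need <- .surv_families[[family]]
  if (!setequal(names(params), need))
    stop(sprintf("family '%s' requires parameters {%s}, got {%s}", family,
                 paste(need, collapse = ", "),
                 paste(names(params), collapse = ", ")))
  params <- params[need]
  if (any(!is.finite(params)))
    stop("non-finite parameter in survival spec")
  pos <- intersect(need, c("rate", "scale", "sdlog", "sigma"))
  if (family %in% c("weibull", "loglogistic", "gamma"))
    pos <- c(pos, "shape")
  if (any(params[pos] <= 0))
    stop(sprintf("parameters {%s} must be strictly positive for family '%s'",
                 paste(pos[params[pos] <= 0], collapse = ", "), family))
  structure(list(family = family, params = params, time_unit = "months"),
            class = "surv_spec")
}

.surv_families <- list(
  exponential = "rate",
  weibull     = c("shape", "scale"),
  loglogistic = c("shape", "scale"),
  lognormal   = c("meanlog", "sdlog"),
  gengamma    = c("mu", "sigma", "Q"),
  gamma       = c("shape", "rate"),
  gompertz    = c("shape", "rate")
)

#' @export
print.surv_spec <- function(x, ...) {
  cat(sprintf("<surv_spec> %s(%s)  [time in %s]\n", x$family,
              paste(sprintf("%s=%.6g", names(x$params), x$params),
                    collapse = ", "), x$time_unit))
  invisible(x)
}

#' Survival, density, hazard and quantile functions
#'
#' \code{psurv} evaluates the survival function S(t); \code{dsurv} the
#' density f(t) (\code{log = TRUE} gives log density); \code{hsurv} the
#' hazard f(t)/S(t); \code{qsurv} inverts S, returning the time at which
#' survival equals \code{p} (so \code{qsurv(spec, runif(n))} draws event
#' times by inverse transform).  All are vectorized over \code{t} / \code{p}.
#'
#' @param spec a \code{surv_spec}.
#' @param t nonnegative times (months).
#' @param p survival probabilities in (0, 1].
#' @param log return log density?
#' @return numeric vector.
#' @export
psurv <- function(spec, t) {
  stopifnot(inherits(spec, "surv_spec"), all(t >= 0))
  p <- spec$params
  unname(switch(spec$family,
    exponential = exp(-p["rate"] * t),
    weibull     = exp(-(t / p["scale"])^p["shape"]),
    loglogistic = 1 / (1 + (t / p["scale"])^p["shape"]),
    lognormal   = .plnorm_surv(t, p["meanlog"], p["sdlog"]),
    gengamma    = .pgg_surv(t, p["mu"], p["sigma"], p["Q"]),
    gamma       = stats::pgamma(t, shape = p["shape"], rate = p["rate"],
                                lower.tail = FALSE),
    gompertz    = .pgomp_surv(t, p["shape"], p["rate"])
  ))
}

.plnorm_surv <- function(t, meanlog, sdlog) {
  s <- numeric(length(t))
  pos <- t > 0
  s[!pos] <- 1
  s[pos] <- stats::pnorm((log(t[pos]) - meanlog) / sdlog, lower.tail = FALSE)
  unname(s)
}

# Prentice generalized gamma: w = (log t - mu)/sigma.
# Q != 0: S = P(Gamma(Q^-2) >= Q^-2 e^{Qw}) for Q > 0, complement for Q < 0.
.pgg_surv <- function(t, mu, sigma, Q) {
  if (abs(Q) < 1e-7) return(.plnorm_surv(t, mu, sigma))
  s <- numeric(length(t))
  pos <- t > 0
  s[!pos] <- 1
  w <- (log(t[pos]) - mu) / sigma
  qq <- Q^-2
  u <- qq * exp(Q * w)
  s[pos] <- if (Q > 0) stats::pgamma(u, shape = qq, lower.tail = FALSE)
            else       stats::pgamma(u, shape = qq, lower.tail = TRUE)
  unname(s)
}

.pgomp_surv <- function(t, shape, rate) {
  if (abs(shape) < 1e-12) return(exp(-rate * t))
  unname(exp(-rate / shape * (exp(shape * t) - 1)))
}

#' @rdname psurv
#' @export
dsurv <- function(spec, t, log = FALSE) {
  stopifnot(inherits(spec, "surv_spec"), all(t >= 0))
  p <- spec$params
  ld <- switch(spec$family,
    exponential = log(p["rate"]) - p["rate"] * t,
    weibull     = stats::dweibull(t, p["shape"], p["scale"], log = TRUE),
    loglogistic = {
      z <- (t / p["scale"])^p["shape"]
      log(p["shape"]) + (p["shape"] - 1) * log(t) -
        p["shape"] * log(p["scale"]) - 2 * log1p(z)
    },
    lognormal   = stats::dlnorm(t, p["meanlog"], p["sdlog"], log = TRUE),
    gengamma    = .dgg_log(t, p["mu"], p["sigma"], p["Q"]),
    gamma       = stats::dgamma(t, shape = p["shape"], rate = p["rate"],
                                log = TRUE),
    gompertz    = log(p["rate"]) + p["shape"] * t +
      (if (abs(p["shape"]) < 1e-12) -p["rate"] * t
       else -p["rate"] / p["shape"] * (exp(p["shape"] * t) - 1))
  )
  ld <- unname(ld)
  if (log) ld else exp(ld)
}

.dgg_log <- function(t, mu, sigma, Q) {
  if (abs(Q) < 1e-7) return(stats::dlnorm(t, mu, sigma, log = TRUE))
  w <- (log(t) - mu) / sigma
  qq <- Q^-2
  log(abs(Q)) + qq * log(qq) - lgamma(qq) - log(sigma) - log(t) +
    qq * (Q * w - exp(Q * w))
}

#' @rdname psurv
#' @export
hsurv <- function(spec, t) {
  dsurv(spec, t) / psurv(spec, t)
}

#' @rdname psurv
#' @export
qsurv <- function(spec, p) {
  stopifnot(inherits(spec, "surv_spec"), all(p > 0), all(p <= 1))
  pr <- spec$params
  out <- switch(spec$family,
    exponential = -log(p) / pr["rate"],
    weibull     = pr["scale"] * (-log(p))^(1 / pr["shape"]),
    loglogistic = pr["scale"] * ((1 - p) / p)^(1 / pr["shape"]),
    lognormal   = stats::qlnorm(p, pr["meanlog"], pr["sdlog"],
                                lower.tail = FALSE),
    gengamma    = .qgg(p, pr["mu"], pr["sigma"], pr["Q"]),
    gamma       = stats::qgamma(p, shape = pr["shape"], rate = pr["rate"],
                                lower.tail = FALSE),
    gompertz    = {
      H <- -log(p)
      if (abs(pr["shape"]) < 1e-12) H / pr["rate"]
      else {
        arg <- 1 + pr["shape"] * H / pr["rate"]
        # negative shape: survival plateaus; quantiles beyond it are infinite
        out <- rep(Inf, length(arg))
        out[arg > 0] <- log(arg[arg > 0]) / pr["shape"]
        out
      }
    }
  )
  unname(out)
}

.qgg <- function(p, mu, sigma, Q) {
  if (abs(Q) < 1e-7)
    return(stats::qlnorm(p, mu, sigma, lower.tail = FALSE))
  qq <- Q^-2
  u <- if (Q > 0) stats::qgamma(p, shape = qq, lower.tail = FALSE)
       else       stats::qgamma(p, shape = qq, lower.tail = TRUE)
  w <- log(u / qq) / Q
  exp(mu + sigma * w)
}

#' Random event times from a survival spec
#'
#' Inverse-transform sampling; used by the synthetic-data generator.
#'
#' @param n number of draws.
#' @param spec a \code{surv_spec}.
#' @return numeric vector of event times (months); may contain \code{Inf}
#'   for plateauing families (negative-shape Gompertz).
#' @export
rsurv <- function(n, spec) {
  qsurv(spec, stats::runif(n))
}
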