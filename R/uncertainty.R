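#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full model with each parameter set to its lower and upper
#' bound in turn, all others held at base, and ranks parameters by the
#' absolute ICER spread.  Parameters whose bounds collapse to the base
#' value produce zero spread; a failed run at a bound is flagged (NA) but
#' the entry is kept.
#'
#' @param pt a \code{\link{param_table}}.
#' @param runner function \code{pt -> ce_result}; defaults to the
#'   base-case pipeline \code{\link{run_cea}}.
#' @param parameters names to vary (default: every parameter with a
#'   nondegenerate range).
#' @return data.frame of class \code{"tornado"} with columns
#'   \code{parameter, low, high, icer_low, icer_high, nmb_low, nmb_high,
#'   spread}, sorted by spread descending.  Attribute \code{"base_icer"}.
#' @export
one_way <- function(pt, runner = run_cea, parameters = NULL) {
  base <- runner(pt)
  df <- pt$params
  if (is.null(parameters))
    parameters <- df$name[df$high > df$low]
  rows <- lapply(parameters, function(nm) {
    i <- match(nm, df$name)
    at <- function(v) {
      p2 <- pt; p2$params$base[i] <- v
      tryCatch(runner(p2), error = function(e) NULL)
    }
    rl <- at(df$low[i]); rh <- at(df$high[i])
    data.frame(parameter = nm, low = df$low[i], high = df$high[i],
               icer_low = if (is.null(rl)) NA_real_ else rl$icer,
               icer_high = if (is.null(rh)) NA_real_ else rh$icer,
               nmb_low = if (is.null(rl)) NA_real_ else rl$nmb,
               nmb_high = if (is.null(rh)) NA_real_ else rh$nmb)
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  class(out) <- c("tornado", "data.frame")
  out
}

#' @export
print.tornado <- function(x, n = 20, ...) {
  cat(sprintf("One-way sensitivity analysis (base ICER $%.2f/QALY); top %d of %d parameters by ICER spread:\n",
              attr(x, "base_icer"), min(n, nrow(x)), nrow(x)))
  print.data.frame(utils::head(cbind(x["parameter"],
                                     round(x[c("icer_low", "icer_high",
                                               "spread")], 1)), n))
  invisible(x)
}

#' Assign the probabilistic-sensitivity distribution of a parameter
#'
#' Distribution classes follow health-economics convention: gamma for
#' costs, beta for proportions and utilities, normal for anthropometrics,
#' uniform over the deterministic range for the discount rate.  Gamma,
#' beta and normal are moment-matched to mean = base value and
#' SD = 10\% of the base value, so a gamma cost always has shape 100 and a
#' beta gets \eqn{\nu = m(1-m)/\sigma^2 - 1}, \eqn{\alpha = m\nu},
#' \eqn{\beta = (1-m)\nu}.
#'
#' @param name parameter name (for error messages).
#' @param base base value.
#' @param low,high deterministic bounds (used by the uniform class).
#' @param psa_class one of gamma, beta, normal, uniform, fixed.
#' @return list with \code{class}, \code{pars} and a sampler
#'   \code{$draw(n)}.
#' @export
assign_psa_distribution <- function(name, base, low, high, psa_class) {
  sd <- 0.1 * base
  switch(psa_class,
    fixed = list(class = "fixed", pars = c(value = base),
                 draw = function(n) rep(base, n)),
    gamma = {
      if (base <= 0) return(list(class = "fixed", pars = c(value = base),
                                 draw = function(n) rep(base, n)))
      shape <- (base / sd)^2          # = 100 by construction
      scale <- base / shape
      list(class = "gamma", pars = c(shape = shape, scale = scale),
           draw = function(n) stats::rgamma(n, shape = shape, scale = scale))
    },
    beta = {
      m <- base
      if (m <= 0 || m >= 1)
        return(list(class = "fixed", pars = c(value = base),
                    draw = function(n) rep(base, n)))
      if (sd^2 >= m * (1 - m))
        stop(sprintf("infeasible beta for '%s': sd^2 >= m(1-m)", name))
      nu <- m * (1 - m) / sd^2 - 1
      a <- m * nu; b <- (1 - m) * nu
      list(class = "beta", pars = c(alpha = a, beta = b),
           draw = function(n) stats::rbeta(n, a, b))
    },
    normal = list(class = "normal", pars = c(mean = base, sd = sd),
                  draw = function(n) stats::rnorm(n, base, sd)),
    uniform = list(class = "uniform", pars = c(min = low, max = high),
                   draw = function(n) stats::runif(n, low, high)),
    stop("unknown psa_class: ", psa_class)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Draws all parameters independently from their assigned distributions
#' (survival-model parameters are not part of the table and therefore stay
#' fixed), runs the full model per draw and summarizes incremental
#' results.  Seeded and reproducible; normal draws for anthropometrics are
#' truncated at zero.
#'
#' @param pt a \code{\link{param_table}}.
#' @param n number of Monte Carlo repetitions (base case 1000).
#' @param seed RNG seed.
#' @param wtp willingness-to-pay threshold for the cost-effectiveness
#'   probability.
#' @param runner function \code{pt -> ce_result}.
#' @return object of class \code{"psa_result"}: \code{samples} data.frame
#'   (one row per draw: delta_cost, delta_qaly, icer, nmb, per-arm cost
#'   and QALY), \code{prob_ce}, \code{wtp}, \code{summary} ranges.
#' @export
run_psa <- function(pt, n = 1000, seed = 1, wtp = 150000,
                    runner = run_cea) {
  df <- pt$params
  dists <- lapply(seq_len(nrow(df)), function(i)
    assign_psa_distribution(df$name[i], df$base[i], df$low[i], df$high[i],
                            df$psa_class[i]))
  old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
  draws <- vapply(dists, function(d) d$draw(n), numeric(n))
  colnames(draws) <- df$name
  # guard supports: nonnegative costs/anthropometrics, probabilities in [0,1]
  pos <- grepl("^(cost_|bsa$|body_weight$)", df$name)
  draws[, pos] <- pmax(draws[, pos], 1e-9)
  prb <- grepl("^(utility_|disutility_|risk_|prop_|p_)", df$name)
  draws[, prb] <- pmin(pmax(draws[, prb], 0), 1)

  samples <- do.call(rbind, lapply(seq_len(n), function(k) {
    p2 <- pt
    p2$params$base <- as.numeric(draws[k, ])
    r <- runner(p2)
    data.frame(delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
               icer = r$icer, nmb = r$wtp * r$delta_qaly - r$delta_cost,
               cost_int = r$intervention$total_cost,
               cost_comp = r$comparator$total_cost,
               qaly_int = r$intervention$total_qaly,
               qaly_comp = r$comparator$total_qaly)
  }))
  samples$nmb <- wtp * samples$delta_qaly - samples$delta_cost
  structure(list(
    samples = samples, n = n, seed = seed, wtp = wtp,
    prob_ce = mean(samples$nmb > 0),
    summary = list(
      icer_range = range(samples$icer),
      cost_int_range = range(samples$cost_int),
      cost_comp_range = range(samples$cost_comp),
      qaly_int_range = range(samples$qaly_int),
      qaly_comp_range = range(samples$qaly_comp))),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d Monte Carlo repetitions (seed %d)\n", x$n,
              x$seed))
  cat(sprintf("  P(cost-effective at $%s/QALY) = %.1f%%\n",
              format(x$wtp, big.mark = ","), 100 * x$prob_ce))
  s <- x$summary
  cat(sprintf("  ICER range  $%.0f - $%.0f\n", s$icer_range[1],
              s$icer_range[2]))
  cat(sprintf("  cost ranges $%.0f-%.0f (intervention) / $%.0f-%.0f (comparator)\n",
              s$cost_int_range[1], s$cost_int_range[2],
              s$cost_comp_range[1], s$cost_comp_range[2]))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA samples with
#' positive net monetary benefit.
#'
#' @param psa a \code{\link{run_psa}} result (or its \code{$samples}).
#' @param lambdas willingness-to-pay grid (USD/QALY).
#' @return data.frame \code{wtp}, \code{prob_ce}.
#' @export
ceac <- function(psa, lambdas = seq(0, 3e5, by = 1e4)) {
  s <- if (inherits(psa, "psa_result")) psa$samples else psa
  data.frame(wtp = lambdas,
             prob_ce = vapply(lambdas, function(l)
               mean(l * s$delta_qaly - s$delta_cost > 0), 0))
}
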