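#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around \code{survival::survfit} returning the step function
#' as plain vectors (with the S(0)=1 anchor prepended), convenient for the
#' digitization and reconstruction round-trip checks.
#'
#' @param ipd an \code{\link{ipd_sample}}.
#' @return object of class \code{"km_curve"}: list with \code{time},
#'   \code{surv} (step values at those times), \code{n}.
#' @export
km_estimator <- function(ipd) {
  stopifnot(inherits(ipd, "ipd_sample"))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(ipd))
  structure(list(time = c(0, sf$time), surv = c(1, sf$surv), n = nrow(ipd)),
            class = "km_curve")
}

#' Evaluate a KM step function at arbitrary times
#' @param km a \code{km_curve}.
#' @param t times.
#' @return survival probabilities (right-continuous step interpolation).
#' @export
km_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$surv[pmax(idx, 1)])
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n=%d, %d steps, S(max)=%.3f at t=%.2f\n",
              x$n, length(x$time) - 1, x$surv[length(x$surv)],
              x$time[length(x$time)]))
  invisible(x)
}

#' Digitized Kaplan-Meier curve
#'
#' Container mirroring what a graph digitizer produces from a published
#' figure: survival coordinates at increasing times plus the number-at-risk
#' row printed under the plot.
#'
#' @param points data.frame with columns \code{time}, \code{survival};
#'   a (0, 1) anchor is prepended if absent.
#' @param risk_table data.frame with columns \code{time}, \code{n_risk}
#'   (nonincreasing positive integers at increasing times).
#' @param total_events optional total event count reported in the source.
#' @return object of class \code{"digitized_curve"}.
#' @export
digitized_curve <- function(points, risk_table, total_events = NULL) {
  stopifnot(all(c("time", "survival") %in% names(points)),
            all(c("time", "n_risk") %in% names(risk_table)))
  points <- points[order(points$time), c("time", "survival")]
  if (points$time[1] > 0)
    points <- rbind(data.frame(time = 0, survival = 1), points)
  if (any(diff(points$time) <= 0)) stop("digitized times must be strictly increasing")
  if (any(points$survival < 0 | points$survival > 1))
    stop("survival coordinates must lie in [0, 1]")
  if (any(diff(points$survival) > 1e-9))
    stop("survival coordinates must be nonincreasing")
  points$survival <- cummin(pmin(points$survival, 1))
  rt <- risk_table[order(risk_table$time), c("time", "n_risk")]
  if (nrow(rt) < 2) stop("need at least 2 risk-table entries")
  if (any(rt$n_risk <= 0) || any(rt$n_risk != round(rt$n_risk)))
    stop("numbers at risk must be positive integers")
  if (any(diff(rt$n_risk) > 0)) stop("numbers at risk must be nonincreasing")
  structure(list(points = points, risk_table = rt,
                 total_events = total_events),
            class = "digitized_curve")
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve> %d coordinates over [0, %.2f] months, %d risk-table rows (n0=%d)\n",
              nrow(x$points), max(x$points$time), nrow(x$risk_table),
              x$risk_table$n_risk[1]))
  invisible(x)
}

#' Digitize a synthetic cohort's Kaplan-Meier curve
#'
#' Emulates manual extraction of coordinates from a published figure:
#' computes the KM estimate, samples it at survival-quantile-spaced times
#' (denser where the curve drops, as a human digitizer clicks), optionally
#' perturbs the ordinates with Gaussian jitter (clipped so monotonicity and
#' the [0,1] range are preserved), and tabulates numbers at risk at fixed
#' calendar intervals.
#'
#' @param ipd an \code{\link{ipd_sample}}.
#' @param n_points number of digitization points (>= 5).
#' @param risk_interval spacing of the risk table in months.
#' @param jitter_sd SD of vertical digitizer error (0 = exact).
#' @param seed optional seed for the jitter.
#' @return a \code{\link{digitized_curve}}.
#' @export
digitize <- function(ipd, n_points = 40, risk_interval = 6, jitter_sd = 0,
                     seed = NULL) {
  stopifnot(n_points >= 5)
  km <- km_estimator(ipd)
  tmax <- max(ipd$time)
  smin <- min(km$surv)
  levels <- seq(1, smin, length.out = n_points + 1)[-1]
  tt <- vapply(levels, function(s) min(c(km$time[km$surv <= s + 1e-12], tmax)),
               0)
  tt <- sort(unique(c(tt, tmax)))
  ss <- km_at(km, tt)
  if (jitter_sd > 0) {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
    }
    ss <- ss + stats::rnorm(length(ss), 0, jitter_sd)
    ss <- pmin(pmax(ss, 0), 1)
    ss <- cummin(ss)                      # restore monotonicity
  }
  rt_times <- seq(0, tmax, by = risk_interval)
  n_risk <- vapply(rt_times, function(a) sum(ipd$time >= a), 0L)
  keep <- n_risk > 0
  digitized_curve(data.frame(time = tt, survival = ss),
                  data.frame(time = rt_times[keep], n_risk = n_risk[keep]),
                  total_events = sum(ipd$event))
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Implementation of the Guyot algorithm: within each interval between
#' consecutive number-at-risk times, integer event and censoring counts are
#' found such that the product-limit estimate of the output tracks the
#' digitized coordinates and the implied numbers at risk match the risk
#' table; censoring times are placed uniformly within intervals.  When the
#' total event count is supplied it is used for the final interval (after
#' the last risk-table time), where censoring is otherwise assumed absent.
#'
#' @param curve a \code{\link{digitized_curve}}.
#' @return an \code{\link{ipd_sample}} of pseudo patient records.
#' @references Guyot P, Ades AE, Ouwens MJ, Welton NJ. Enhanced secondary
#'   analysis of survival data: reconstructing the data from published
#'   Kaplan-Meier survival curves. BMC Med Res Methodol 2012;12:9.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  t <- curve$points$time
  S <- curve$points$survival
  K <- length(t)
  trisk <- curve$risk_table$time
  nrisk <- curve$risk_table$n_risk
  J <- length(trisk)
  # lower[j]: first digitized index at/after trisk[j]
  lower <- vapply(seq_len(J), function(j) {
    w <- which(t >= trisk[j] - 1e-9)
    if (length(w)) w[1] else K + 1L
  }, 0L)
  upper <- c(lower[-1] - 1L, K)
  if (lower[1] > 1) stop("risk table starts after the first digitized point")

  n <- numeric(K + 1)          # at risk entering each digitized time
  d <- integer(K)              # events at t[k]
  cen <- integer(K)            # censorings in (t[k], t[k+1])
  cen_times <- vector("list", K)
  KMhat <- numeric(K)          # reconstructed KM at t[k]
  n[lower[1]] <- nrisk[1]

  run_interval <- function(j, ncen_j, n, d, cen, cen_times, KMhat, last, prodKM) {
    lo <- lower[j]; up <- upper[j]
    t_end <- if (j < J) trisk[j + 1] else max(t[up], trisk[j])
    # distribute ncen_j censor times uniformly over the interval
    ct <- if (ncen_j > 0)
      trisk[j] + (seq_len(ncen_j) - 0.5) / ncen_j * (t_end - trisk[j])
    else numeric(0)
    for (k in lo:up) {
      if (n[k] <= 0) { d[k] <- 0L; cen[k] <- 0L; cen_times[[k]] <- numeric(0)
                       KMhat[k] <- prodKM; n[k + 1] <- 0; next }
      dk <- round(n[k] * (1 - S[k] / prodKM))
      dk <- max(0L, min(as.integer(dk), n[k]))
      if (dk > 0) prodKM <- prodKM * (1 - dk / n[k])
      d[k] <- dk
      KMhat[k] <- prodKM
      up_t <- if (k < K) t[k + 1] else Inf
      # hand out pooled censor times due by the next digitized point, capped
      # by the remaining risk set; undistributed ones roll over
      avail <- which(ct <= up_t + 1e-12)
      take <- utils::head(avail, max(0L, n[k] - dk))
      cen[k] <- length(take)
      cen_times[[k]] <- pmax(ct[take], t[k])
      if (length(take)) ct <- ct[-take]
      n[k + 1] <- n[k] - d[k] - cen[k]
    }
    list(n = n, d = d, cen = cen, cen_times = cen_times, KMhat = KMhat,
         prodKM = prodKM, n_end = n[up + 1])
  }

  prodKM <- 1
  extra_cens <- list()   # censor-only allocations for point-free intervals
  for (j in seq_len(J)) {
    lo <- lower[j]; up <- upper[j]
    if (lo > up) {
      # no digitized coordinates in this risk interval: the at-risk drop can
      # only be censoring, placed uniformly across the interval
      if (j < J) {
        entering <- if (j == 1) nrisk[1] else nrisk[j]
        ncen <- max(0L, as.integer(round(entering - nrisk[j + 1])))
        if (ncen > 0)
          extra_cens[[length(extra_cens) + 1]] <-
            trisk[j] + (seq_len(ncen) - 0.5) / ncen * (trisk[j + 1] - trisk[j])
        if (lower[j + 1] <= K) n[lower[j + 1]] <- nrisk[j + 1]
      }
      next
    }
    n_enter <- n[lo]
    if (n_enter == 0) n_enter <- n[lo] <- nrisk[j]
    if (j < J) {
      target <- nrisk[j + 1]
      ncen_j <- 0L
      best <- NULL
      # Guyot iteration: adjust interval censoring until the implied number
      # at risk at the next risk time matches the risk table.
      for (iter in 1:50) {
        res <- run_interval(j, ncen_j, n, d, cen, cen_times, KMhat, NULL, prodKM)
        gap <- res$n_end - target
        if (is.null(best) || abs(gap) < abs(best$gap))
          best <- c(res, list(gap = gap, ncen = ncen_j))
        if (gap == 0) break
        ncen_new <- ncen_j + gap
        ncen_new <- max(0L, min(as.integer(ncen_new), n_enter))
        if (ncen_new == ncen_j) break
        ncen_j <- ncen_new
      }
      n <- best$n; d <- best$d; cen <- best$cen
      cen_times <- best$cen_times; KMhat <- best$KMhat
      # reconcile exactly with the published number at risk: absorb any
      # residual gap into censoring (preferred) or the latest events
      delta <- as.integer(best$gap)
      if (delta > 0) {
        tlo <- max(t[up], trisk[j])
        thi <- trisk[j + 1]
        cen[up] <- cen[up] + delta
        cen_times[[up]] <- c(cen_times[[up]],
                             tlo + (seq_len(delta) - 0.5) / delta * (thi - tlo))
      } else if (delta < 0) {
        need <- -delta
        for (k in up:lo) {
          take <- min(need, cen[k])
          if (take > 0) {
            cen[k] <- cen[k] - take
            cen_times[[k]] <- utils::head(cen_times[[k]], cen[k])
            need <- need - take
          }
          if (need == 0) break
        }
        if (need > 0) for (k in up:lo) {
          take <- min(need, d[k])
          d[k] <- d[k] - take
          need <- need - take
          if (need == 0) break
        }
        if (need > 0)
          warning(sprintf(
            "risk table inconsistent in interval %d [%g, %g): short %d at risk",
            j, trisk[j], trisk[j + 1], need))
      }
      # recompute the at-risk chain and KM product over the interval
      for (k in lo:up) n[k + 1] <- n[k] - d[k] - cen[k]
      prodKM_in <- prodKM
      for (k in lo:up) if (d[k] > 0 && n[k] > 0)
        prodKM_in <- prodKM_in * (1 - d[k] / n[k])
      prodKM <- prodKM_in
      n[lower[j + 1]] <- target
    } else {
      # final interval: no further risk anchor; assume no censoring unless
      # a total event count pins it down
      res <- run_interval(j, 0L, n, d, cen, cen_times, KMhat, NULL, prodKM)
      n <- res$n; d <- res$d; cen <- res$cen
      cen_times <- res$cen_times; KMhat <- res$KMhat; prodKM <- res$prodKM
      if (!is.null(curve$total_events)) {
        lack <- curve$total_events - sum(d)
        if (lack != 0 && n[K + 1] > 0) {
          add <- max(0L, min(as.integer(lack), n[K + 1]))
          d[K] <- d[K] + add
          n[K + 1] <- n[K + 1] - add
        }
      }
    }
  }

  all_cens <- c(unlist(cen_times), unlist(extra_cens))
  times <- c(rep(t, d), all_cens)
  events <- c(rep(1L, sum(d)), rep(0L, length(all_cens)))
  # survivors past the last digitized point are censored there
  if (n[K + 1] > 0) {
    times <- c(times, rep(max(t), n[K + 1]))
    events <- c(events, rep(0L, n[K + 1]))
  }
  keep <- times > 0
  ipd_sample(times[keep], events[keep])
}

#' Read a digitized curve from CSV files
#' @param points_path CSV with columns time, survival.
#' @param risk_path CSV with columns time, n_risk.
#' @param total_events optional count.
#' @return a \code{\link{digitized_curve}}.
#' @export
read_digitized_curve <- function(points_path, risk_path, total_events = NULL) {
  digitized_curve(utils::read.csv(points_path), utils::read.csv(risk_path),
                  total_events)
}
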