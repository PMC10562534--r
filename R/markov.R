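#' @title Five-state Markov cohort engine
#' @description
#' The disease model is a cohort Markov chain over the ordered states
#' NEOADJ (neoadjuvant treatment), POST_SURG_RT (post-surgery /
#' radiotherapy residency), ADJUVANT (adjuvant immunotherapy), PD
#' (progressive disease) and DEATH (absorbing), advanced in 21-day cycles.
#' Transition probabilities are time-varying and derived from the fitted
#' overall-survival and event-free-survival curves of each arm: death is
#' applied uniformly across alive states at the OS-derived conditional
#' probability (optionally floored by general-population mortality), which
#' makes cohort-level survival reproduce the fitted OS curve; progression
#' receives the remainder of the EFS-derived event probability.  The
#' NEOADJ to POST_SURG_RT transition is open only during the surgery
#' window (cycles 5-6) and the POST_SURG_RT to ADJUVANT transition only
#' during the adjuvant window (cycles 6-10), mirroring the trial schedule.
#' @name markov_engine
NULL

.states <- c("NEOADJ", "POST_SURG_RT", "ADJUVANT", "PD", "DEATH")

#' Model time constants: 21-day cycles expressed in months and years
#' @export
cycle_length_months <- 21 / 30.4375
#' @rdname cycle_length_months
#' @export
cycle_length_years <- 21 / 365.25

#' Engine configuration
#'
#' Bundles everything a cohort run needs: the parameter table, per-arm
#' survival specs, horizon, cycle windows and the accrual conventions.
#'
#' @param pt a \code{\link{param_table}}.
#' @param surv_specs per-arm survival specs as from
#'   \code{\link{base_survival_specs}}.
#' @param horizon_years analytic time horizon (default 10 years = 174
#'   cycles).
#' @param window_neo_to_surg inclusive cycle interval in which the surgery
#'   transition is open (1-based; transition at end of cycle).
#' @param window_surg_to_adj inclusive cycle interval for adjuvant entry
#'   (intervention arm only).
#' @param adjuvant_max_cycles administrations of adjuvant therapy before
#'   exit to follow-up residency.
#' @param pd_chemo_cycles cycles of palliative chemotherapy after
#'   progression.
#' @param bg_mortality floor the death probability with general-population
#'   mortality (\code{\link{background_mortality_table}})?
#' @param half_cycle use the half-cycle (life-table) occupancy correction
#'   for residency accrual?
#' @param bsc_days_per_charge calendar days covered by one best-supportive
#'   -care charge (accrual periodicity of the \code{cost_bsc} value).
#' @param fu_days_per_charge calendar days covered by one follow-up charge.
#' @param reg a \code{\link{regimen}}.
#' @return list of class \code{"engine_config"}.
#' @export
engine_config <- function(pt, surv_specs = base_survival_specs(),
                          horizon_years = 10,
                          window_neo_to_surg = c(5, 6),
                          window_surg_to_adj = c(6, 10),
                          adjuvant_max_cycles = 13,
                          pd_chemo_cycles = 6,
                          bg_mortality = TRUE,
                          half_cycle = TRUE,
                          bsc_days_per_charge = 91.3125,
                          fu_days_per_charge = 21,
                          reg = regimen()) {
  stopifnot(inherits(pt, "param_table"))
  horizon_cycles <- round(horizon_years * 365.25 / 21)
  if (horizon_cycles < 10) stop("horizon must cover at least 10 cycles")
  if (window_surg_to_adj[2] > horizon_cycles ||
      window_neo_to_surg[2] > horizon_cycles)
    stop("cycle windows must lie within the horizon")
  arms <- names(surv_specs)
  if (!all(c("os", "efs") %in% names(surv_specs[[1]])))
    stop("each arm needs os and efs survival specs")
  structure(list(
    pt = pt, surv_specs = surv_specs, arms = arms, intervention = arms[1],
    horizon_years = horizon_years, horizon_cycles = horizon_cycles,
    window_neo_to_surg = window_neo_to_surg,
    window_surg_to_adj = window_surg_to_adj,
    adjuvant_max_cycles = adjuvant_max_cycles,
    pd_chemo_cycles = pd_chemo_cycles,
    bg_mortality = bg_mortality, half_cycle = half_cycle,
    bsc_days_per_charge = bsc_days_per_charge,
    fu_days_per_charge = fu_days_per_charge,
    reg = reg, bg_table = background_mortality_table()),
    class = "engine_config")
}

#' Conditional transition probability from a survival curve
#'
#' Probability of the event in \code{(t, t + dt]} given event-free at
#' \code{t}: \code{1 - S(t + dt) / S(t)}.  Returns 1 once the curve is
#' exhausted (\code{S(t) = 0}).
#'
#' @param spec a \code{\link{surv_spec}}.
#' @param t current time (months).
#' @param dt cycle length (months).
#' @return probability in [0, 1].
#' @export
conditional_transition_prob <- function(spec, t, dt) {
  s0 <- psurv(spec, t)
  if (s0 <= 0) return(1)
  p <- 1 - psurv(spec, t + dt) / s0
  min(max(p, 0), 1)
}

# per-cycle hazards for cycle `cycle` (1-based): death and progression
.cycle_probs <- function(cfg, arm, cycle) {
  dt <- cycle_length_months
  t0 <- (cycle - 1) * dt
  sp <- cfg$surv_specs[[arm]]
  pdth <- conditional_transition_prob(sp$os, t0, dt)
  if (cfg$bg_mortality) {
    age <- cfg$pt$cohort$age_years + t0 / 12
    qx <- .bg_qx(cfg$bg_table, age)
    pbg <- 1 - (1 - qx)^cycle_length_years
    pdth <- max(pdth, pbg)
  }
  pev <- conditional_transition_prob(sp$efs, t0, dt)
  ppd <- max(0, pev - pdth)
  if (pdth + ppd > 1) ppd <- 1 - pdth
  c(pdth = pdth, ppd = ppd)
}

# window transition probabilities: geometric split so the cumulative moved
# fraction over the open window equals the configured proportion
.window_prob <- function(prop, window) {
  len <- window[2] - window[1] + 1
  1 - (1 - prop)^(1 / len)
}

#' Per-cycle transition matrix
#'
#' Builds the 5x5 row-stochastic matrix for one cycle of one arm.  The
#' surgery window additionally charges 30-day operative mortality to the
#' surgical fraction of movers; the ADJUVANT row needs the share of its
#' occupancy that has completed the final adjuvant administration
#' (\code{adj_exit_frac}), which the cohort loop tracks by time in state.
#'
#' @param cycle 1-based cycle index.
#' @param cfg an \code{\link{engine_config}}.
#' @param arm arm label.
#' @param adj_exit_frac fraction of current ADJUVANT occupancy at the last
#'   adjuvant cycle (exits to POST_SURG_RT on survival).
#' @return 5x5 matrix with rows summing to 1.
#' @export
build_transition_matrix <- function(cycle, cfg, arm, adj_exit_frac = 0) {
  if (cycle > cfg$horizon_cycles) stop("cycle beyond horizon")
  pr <- .cycle_probs(cfg, arm, cycle)
  pdth <- pr["pdth"]; ppd <- pr["ppd"]
  s <- 1 - pdth - ppd
  w1 <- cfg$window_neo_to_surg; w2 <- cfg$window_surg_to_adj
  prop_key <- if (arm == cfg$intervention) "prop_local_therapy_pem" else
    "prop_local_therapy_placebo"
  qs <- if (cycle >= w1[1] && cycle <= w1[2])
    .window_prob(pt_value(cfg$pt, prop_key), w1) else 0
  qa <- if (arm == cfg$intervention && cycle >= w2[1] && cycle <= w2[2])
    .window_prob(pt_value(cfg$pt, "prop_adjuvant_uptake"), w2) else 0
  psm <- pt_value(cfg$pt, "prop_surgery_among_local") *
    pt_value(cfg$pt, "p_surgery_mortality_30d")
  M <- matrix(0, 5, 5, dimnames = list(.states, .states))
  M["NEOADJ", ] <- c(s * (1 - qs), s * qs * (1 - psm), 0, ppd,
                     pdth + s * qs * psm)
  M["POST_SURG_RT", ] <- c(0, s * (1 - qa), s * qa, ppd, pdth)
  M["ADJUVANT", ] <- c(0, s * adj_exit_frac, s * (1 - adj_exit_frac), ppd,
                       pdth)
  M["PD", ] <- c(0, 0, 0, 1 - pdth, pdth)
  M["DEATH", ] <- c(0, 0, 0, 0, 1)
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12))
    stop("internal error: transition-matrix row sums deviate from 1")
  M
}

#' Run the cohort simulation for one arm
#'
#' Starts the whole cohort in NEOADJ and advances it through the
#' time-varying transition matrices, tracking state occupancy, per-cycle
#' entrant counts (for one-off cost attribution) and the start-of-cycle
#' occupancies eligible for drug administration (neoadjuvant cycles 1-4,
#' adjuvant administrations 1-13, first 6 post-progression chemotherapy
#' cycles).  Time in the ADJUVANT and PD states is tracked exactly via
#' age-in-state vectors, so the 5-state trace needs no tunnel states.
#'
#' @param cfg an \code{\link{engine_config}}.
#' @param arm arm label (one of \code{cfg$arms}).
#' @return object of class \code{"cohort_trace"}: list with
#'   \code{occupancy} ((H+1) x 5 matrix, row 1 = cycle 0),
#'   \code{entrants} (H x 4: local therapy, adjuvant, PD, death),
#'   \code{drug_occ} (H x 3: neoadjuvant, adjuvant, PD-chemo eligible
#'   start-of-cycle occupancy), \code{arm}, \code{cfg}.
#' @export
run_cohort <- function(cfg, arm) {
  stopifnot(inherits(cfg, "engine_config"))
  arm <- match.arg(arm, cfg$arms)
  H <- cfg$horizon_cycles
  K <- cfg$adjuvant_max_cycles
  P <- cfg$pd_chemo_cycles
  occ <- matrix(0, H + 1, 5, dimnames = list(NULL, .states))
  occ[1, 1] <- 1
  ent <- matrix(0, H, 4,
                dimnames = list(NULL, c("local", "adjuvant", "pd", "death")))
  drug <- matrix(0, H, 3, dimnames = list(NULL, c("neoadj", "adj", "pd_chemo")))
  adj_age <- numeric(K)
  pd_age <- numeric(P)
  w1 <- cfg$window_neo_to_surg; w2 <- cfg$window_surg_to_adj
  for (cc in seq_len(H)) {
    prev <- occ[cc, ]
    adj_tot <- sum(adj_age)
    exit_frac <- if (adj_tot > 0) adj_age[K] / adj_tot else 0
    M <- build_transition_matrix(cc, cfg, arm, adj_exit_frac = exit_frac)
    occ[cc + 1, ] <- prev %*% M
    s <- M["PD", "PD"] - 0  # survive-and-stay prob for PD row is 1-pdth
    pdth <- M["POST_SURG_RT", "DEATH"]
    surv_ev <- M["POST_SURG_RT", "POST_SURG_RT"] + M["POST_SURG_RT", "ADJUVANT"]
    ent[cc, "local"] <- prev["NEOADJ"] *
      (M["NEOADJ", "POST_SURG_RT"] + M["NEOADJ", "DEATH"] - pdth)
    # the DEATH excess over pdth is operative mortality among movers; the
    # full mover mass (including operative deaths) receives local therapy
    ent[cc, "adjuvant"] <- prev["POST_SURG_RT"] * M["POST_SURG_RT", "ADJUVANT"]
    ent[cc, "pd"] <- (prev["NEOADJ"] + prev["POST_SURG_RT"] +
                        prev["ADJUVANT"]) * M["POST_SURG_RT", "PD"]
    ent[cc, "death"] <- occ[cc + 1, "DEATH"] - prev["DEATH"]
    drug[cc, "neoadj"] <- if (cc <= 4) prev["NEOADJ"] else 0
    drug[cc, "adj"] <- adj_tot
    drug[cc, "pd_chemo"] <- sum(pd_age)
    adj_age <- c(ent[cc, "adjuvant"], adj_age[-K] * surv_ev)
    pd_age <- c(ent[cc, "pd"], pd_age[-P] * (1 - pdth))
  }
  structure(list(occupancy = occ, entrants = ent, drug_occ = drug,
                 arm = arm, cfg = cfg),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- nrow(x$occupancy) - 1
  cat(sprintf("<cohort_trace> arm '%s', %d cycles (%.1f years)\n", x$arm, H,
              H * cycle_length_years))
  cat(sprintf("  alive at horizon: %.4f; ever progressed: %.4f; surgery/RT: %.4f\n",
              1 - x$occupancy[H + 1, "DEATH"], sum(x$entrants[, "pd"]),
              sum(x$entrants[, "local"])))
  invisible(x)
}

#' Export a trace as a per-cycle data.frame
#' @param x a \code{cohort_trace}.
#' @param ... unused.
#' @return data.frame with cycle, state occupancies and entrant columns.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  H <- nrow(x$occupancy) - 1
  cbind(data.frame(cycle = 0:H), as.data.frame(x$occupancy),
        rbind(NA, as.data.frame(x$entrants)))
}

#' Patient-level micro-simulation oracle
#'
#' Simulates individual walkers through the same per-cycle transition
#' matrices used by the cohort trace.  Used in tests to verify that the
#' deterministic trace equals the Monte-Carlo state frequencies within
#' sampling error; not a production path.
#'
#' @param cfg an \code{\link{engine_config}}.
#' @param arm arm label.
#' @param n_walkers number of simulated patients.
#' @param seed RNG seed.
#' @return (H+1) x 5 matrix of state frequencies.
#' @export
microsim_occupancy <- function(cfg, arm, n_walkers = 1e6, seed = 1) {
  arm <- match.arg(arm, cfg$arms)
  H <- cfg$horizon_cycles
  K <- cfg$adjuvant_max_cycles
  old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed)
  # counts per state, with ADJUVANT split by age in state
  counts <- c(n_walkers, 0, 0, 0, 0)
  adj_age <- integer(K)
  freq <- matrix(0, H + 1, 5, dimnames = list(NULL, .states))
  freq[1, ] <- counts / n_walkers
  for (cc in seq_len(H)) {
    adj_tot <- sum(adj_age)
    exit_frac <- if (adj_tot > 0) adj_age[K] / adj_tot else 0
    M <- build_transition_matrix(cc, cfg, arm, adj_exit_frac = exit_frac)
    newc <- c(0, 0, 0, 0, 0)
    new_adj <- integer(K)
    for (s in 1:5) {
      if (counts[s] == 0) next
      if (s == 3) {
        # draw each adjuvant age class separately: only the final class exits
        surv_ev <- M[3, 2] + M[3, 3]
        for (a in seq_len(K)) {
          if (adj_age[a] == 0) next
          p <- c(0, 0, 0, M[3, 4], M[3, 5])
          if (a == K) p[2] <- surv_ev else p[3] <- surv_ev
          drawn <- stats::rmultinom(1, adj_age[a], p)[, 1]
          newc <- newc + drawn
          if (a < K) new_adj[a + 1] <- drawn[3]
        }
      } else {
        drawn <- stats::rmultinom(1, counts[s], M[s, ])[, 1]
        newc <- newc + drawn
        if (s == 2) new_adj[1] <- drawn[3]
      }
    }
    counts <- newc
    adj_age <- new_adj
    counts[3] <- sum(adj_age)
    freq[cc + 1, ] <- counts / n_walkers
  }
  freq
}
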