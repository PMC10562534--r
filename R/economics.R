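#' Per-cycle discount factor
#'
#' Continuous-compounding-free annual discounting applied at cycle
#' granularity: \code{(1 + rate)^(-cycle * 21 / 365.25)}.
#'
#' @param rate_annual annual discount rate (base case 0.03).
#' @param cycle cycle index (vectorized); \code{cycle = 0} gives 1.
#' @return discount factor(s).
#' @export
per_cycle_discount <- function(rate_annual, cycle) {
  stopifnot(rate_annual >= 0)
  (1 + rate_annual)^(-cycle * cycle_length_years)
}

# --- drug / administration unit costs -------------------------------------

# Cost of one neoadjuvant chemotherapy administration cycle (without
# pembrolizumab): cisplatin + histology-weighted partner agent, plus
# infusion fees.  Gemcitabine's day-8 visit is billed a first infusion hour.
.chemo_cycle_cost <- function(pt, reg) {
  bsa <- pt_value(pt, "bsa")
  f <- pt_value(pt, "prop_nonsquamous")
  drug <- reg$cisplatin_mg_m2 * bsa * pt_value(pt, "cost_cisplatin_mg") +
    f * reg$pemetrexed_mg_m2 * bsa * pt_value(pt, "cost_pemetrexed_mg") +
    (1 - f) * reg$gemcitabine_mg_m2 * bsa * reg$gemcitabine_admin_per_cycle *
      pt_value(pt, "cost_gemcitabine_mg")
  inf <- pt_value(pt, "cost_infusion_first_hr") +
    pt_value(pt, "cost_infusion_addl_hr") +
    pt_value(pt, "cost_infusion_subseq_hr") +
    (1 - f) * (reg$gemcitabine_admin_per_cycle - 1) *
      pt_value(pt, "cost_infusion_first_hr")
  c(drug = unname(drug), infusion = unname(inf))
}

.pembro_admin_cost <- function(pt, reg) {
  unname(reg$pembrolizumab_mg * pt_value(pt, "cost_pembrolizumab_mg"))
}

# expected one-off severe-adverse-event cost / QALY decrement for an arm
.sae_burden <- function(pt, arm_suffix) {
  risks <- pt_value(pt, paste0(c("risk_anemia_", "risk_neutropenia_",
                                 "risk_thrombocytopenia_"), arm_suffix))
  costs <- pt_value(pt, c("cost_sae_anemia", "cost_sae_neutropenia",
                          "cost_sae_thrombocytopenia"))
  disut <- pt_value(pt, c("disutility_anemia", "disutility_neutropenia",
                          "disutility_thrombocytopenia"))
  c(cost = sum(risks * costs),
    qaly = sum(risks * disut) * cycle_length_years)
}

#' Accrue costs and QALYs over a cohort trace
#'
#' Walks the trace cycle by cycle: drug and administration costs are
#' charged on start-of-cycle treated occupancy; residency costs (best
#' supportive care in PD, routine follow-up in post-treatment
#' progression-free residency) and utilities use half-cycle-corrected
#' occupancy; one-off costs (surgery/radiotherapy, radiotherapy at
#' progression, end-of-life care) attach to per-cycle entrant counts; the
#' expected severe-adverse-event cost and QALY decrement are charged once
#' in cycle 1.  Everything is accumulated discounted and undiscounted,
#' with a per-category cost ledger.
#'
#' @param trace a \code{\link{run_cohort}} result.
#' @param pt parameter table (defaults to the one inside the trace config;
#'   passing a modified table supports sensitivity analyses).
#' @return object of class \code{"arm_result"}.
#' @export
accrue <- function(trace, pt = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  cfg <- trace$cfg
  if (is.null(pt)) pt <- cfg$pt
  H <- cfg$horizon_cycles
  is_int <- trace$arm == cfg$intervention
  occ <- trace$occupancy
  ent <- trace$entrants
  drug <- trace$drug_occ
  v <- per_cycle_discount(pt_value(pt, "discount_rate"), seq_len(H))

  w_occ <- if (cfg$half_cycle) (occ[1:H, ] + occ[2:(H + 1), ]) / 2
           else occ[2:(H + 1), ]

  chemo <- .chemo_cycle_cost(pt, cfg$reg)
  pem_admin <- .pembro_admin_cost(pt, cfg$reg)
  first_hr <- pt_value(pt, "cost_infusion_first_hr")
  bsc_rate <- pt_value(pt, "cost_bsc") * 21 / cfg$bsc_days_per_charge
  fu_rate <- pt_value(pt, "cost_follow_up") * 21 / cfg$fu_days_per_charge
  psl <- pt_value(pt, "prop_surgery_among_local")
  local_cost <- psl * pt_value(pt, "cost_surgery_event") +
    (1 - psl) * pt_value(pt, "cost_radiotherapy_event")
  sae <- .sae_burden(pt, if (is_int) "pem" else "placebo")

  cat_cycle <- cbind(
    drug_pembrolizumab = if (is_int)
      (drug[, "neoadj"] + drug[, "adj"]) * pem_admin else numeric(H),
    drug_chemotherapy = (drug[, "neoadj"] + drug[, "pd_chemo"]) *
      chemo["drug"],
    infusion = (drug[, "neoadj"] + drug[, "pd_chemo"]) * chemo["infusion"] +
      (if (is_int) drug[, "adj"] * first_hr else numeric(H)),
    surgery_radiotherapy = ent[, "local"] * local_cost,
    pd_radiotherapy = ent[, "pd"] * pt_value(pt, "cost_radiotherapy_event"),
    best_supportive_care = w_occ[, "PD"] * bsc_rate,
    follow_up = (w_occ[, "POST_SURG_RT"] +
                   ifelse(seq_len(H) > cfg$window_neo_to_surg[2],
                          w_occ[, "NEOADJ"], 0)) * fu_rate,
    end_of_life = ent[, "death"] * pt_value(pt, "cost_end_of_life"),
    sae_management = c(sae["cost"], numeric(H - 1))
  )

  u <- c(NEOADJ = unname(pt_value(pt, "utility_pf")),
         POST_SURG_RT = unname(psl * pt_value(pt, "utility_surgery") +
                                 (1 - psl) * pt_value(pt, "utility_radiotherapy")),
         ADJUVANT = unname(pt_value(pt, "utility_pf")),
         PD = unname(pt_value(pt, "utility_pd")),
         DEATH = 0)
  qaly_cycle <- as.numeric(w_occ %*% u) * cycle_length_years
  qaly_cycle[1] <- qaly_cycle[1] - sae["qaly"]

  breakdown <- colSums(cat_cycle * v)
  breakdown_undisc <- colSums(cat_cycle)
  structure(list(
    arm = trace$arm,
    total_cost = sum(breakdown), total_qaly = sum(qaly_cycle * v),
    undiscounted_cost = sum(breakdown_undisc),
    undiscounted_qaly = sum(qaly_cycle),
    life_years = sum((1 - w_occ[, "DEATH"])) * cycle_length_years,
    breakdown = breakdown), class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s: cost $%.1f, %.4f QALY (undiscounted $%.1f, %.4f QALY; %.2f LY)\n",
              x$arm, x$total_cost, x$total_qaly, x$undiscounted_cost,
              x$undiscounted_qaly, x$life_years))
  b <- x$breakdown
  for (nm in names(b)) cat(sprintf("  %-22s $%12.2f\n", nm, b[[nm]]))
  invisible(x)
}

#' Incremental cost-effectiveness comparison
#'
#' @param intervention,comparator \code{arm_result}s accrued on the same
#'   configuration.
#' @param wtp willingness-to-pay threshold in USD per QALY gained.
#' @return object of class \code{"ce_result"} with \code{delta_cost},
#'   \code{delta_qaly}, \code{icer} (NA with a flag when the QALY delta is
#'   zero or the intervention dominates/is dominated), \code{nmb} and a
#'   \code{dominance} label.
#' @export
compare <- function(intervention, comparator, wtp = 150000) {
  stopifnot(inherits(intervention, "arm_result"),
            inherits(comparator, "arm_result"))
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly
  dominance <- if (dc < 0 && de > 0) "dominant"
               else if (dc > 0 && de < 0) "dominated"
               else "none"
  icer <- if (de == 0) NA_real_ else dc / de
  structure(list(
    arms = c(intervention$arm, comparator$arm),
    delta_cost = dc, delta_qaly = de, icer = icer,
    nmb = wtp * de - dc, wtp = wtp, dominance = dominance,
    intervention = intervention, comparator = comparator),
    class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness: %s vs %s\n", x$arms[1], x$arms[2]))
  tab <- data.frame(
    cost = c(x$intervention$total_cost, x$comparator$total_cost),
    qaly = c(x$intervention$total_qaly, x$comparator$total_qaly),
    row.names = x$arms)
  print(round(tab, 3))
  cat(sprintf("  Incremental cost  $%.1f\n  Incremental QALY  %.6f\n",
              x$delta_cost, x$delta_qaly))
  if (is.na(x$icer)) {
    cat("  ICER undefined (zero QALY difference)\n")
  } else cat(sprintf("  ICER              $%.2f per QALY\n", x$icer))
  cat(sprintf("  NMB at $%s/QALY: $%.1f", format(x$wtp, big.mark = ","),
              x$nmb))
  if (x$dominance != "none") cat("  [", x$dominance, "]")
  cat("\n")
  invisible(x)
}
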