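#' Model parameter table
#'
#' Typed container for every scalar model input: base value, deterministic
#' sensitivity range and probabilistic-sensitivity distribution class.
#' The packaged base case (see \code{\link{table1_fixture}}) carries drug
#' unit prices, per-event and per-cycle costs, state utilities, severe
#' adverse event risks and disutilities, cohort anthropometrics and the
#' treatment-pathway proportions.
#'
#' @param df data.frame with columns \code{name}, \code{base}, \code{low},
#'   \code{high}, \code{psa_class} (one of gamma, beta, normal, uniform,
#'   fixed), \code{units}.
#' @param arm_labels character pair of strategy names.
#' @param age_years cohort age at model entry.
#' @return object of class \code{"param_table"}.
#' @export
param_table <- function(df, arm_labels = c("pembrolizumab", "placebo"),
                        age_years = 65) {
  need <- c("name", "base", "low", "high", "psa_class", "units")
  if (!all(need %in% names(df)))
    stop("parameter table needs columns ", paste(need, collapse = ", "))
  df <- df[need]
  df$name <- as.character(df$name)
  if (anyDuplicated(df$name)) stop("duplicate parameter names")
  bad <- !df$psa_class %in% c("gamma", "beta", "normal", "uniform", "fixed")
  if (any(bad)) stop("unknown psa_class for: ",
                     paste(df$name[bad], collapse = ", "))
  .validate_params(df)
  pt <- structure(list(params = df, arm_labels = arm_labels,
                       cohort = list(age_years = age_years)),
                  class = "param_table")
  cw <- tryCatch(c(pt_value(pt, "body_weight"), pt_value(pt, "bsa")),
                 error = function(e) c(1, 1))
  if (any(cw <= 0)) stop("cohort anthropometrics must be positive")
  pt
}

.validate_params <- function(df) {
  ok_rng <- is.na(df$low) | is.na(df$high) |
    (df$low <= df$base + 1e-12 & df$base <= df$high + 1e-12)
  if (any(!ok_rng))
    stop("range does not bracket base value for: ",
         paste(df$name[!ok_rng], collapse = ", "),
         " (low <= base <= high required)")
  prob_like <- grepl("^(utility_|disutility_|risk_|prop_|p_)", df$name) |
    df$name == "discount_rate"
  bad <- prob_like & (df$base < 0 | df$base > 1)
  if (any(bad))
    stop("probabilities/utilities must lie in [0,1]: ",
         paste(df$name[bad], collapse = ", "))
  costs <- grepl("^cost_", df$name)
  if (any(costs & df$base < 0))
    stop("costs must be nonnegative: ",
         paste(df$name[costs & df$base < 0], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.param_table <- function(x, ...) {
  cat(sprintf("<param_table> %d parameters; arms: %s vs %s; cohort age %d\n",
              nrow(x$params), x$arm_labels[1], x$arm_labels[2],
              x$cohort$age_years))
  invisible(x)
}

#' @export
as.data.frame.param_table <- function(x, ...) x$params

#' Look up a parameter base value
#'
#' Missing keys are an error, never a silent default.
#'
#' @param pt a \code{param_table}.
#' @param name parameter name(s).
#' @return named numeric vector of base values.
#' @export
pt_value <- function(pt, name) {
  i <- match(name, pt$params$name)
  if (anyNA(i))
    stop("parameter(s) not found in table: ",
         paste(name[is.na(i)], collapse = ", "))
  stats::setNames(pt$params$base[i], name)
}

#' Replace parameter base values
#' @param pt a \code{param_table}.
#' @param values named numeric vector of new base values.
#' @return modified \code{param_table}.
#' @export
pt_set <- function(pt, values) {
  i <- match(names(values), pt$params$name)
  if (anyNA(i))
    stop("parameter(s) not found in table: ",
         paste(names(values)[is.na(i)], collapse = ", "))
  pt$params$base[i] <- as.numeric(values)
  # widen stale bounds so ad-hoc overrides (scenarios) stay valid
  pt$params$low[i] <- pmin(pt$params$low[i], pt$params$base[i])
  pt$params$high[i] <- pmax(pt$params$high[i], pt$params$base[i])
  pt
}

.mandatory_params <- function() {
  c("body_weight", "bsa", "discount_rate", "p_surgery_mortality_30d",
    "cost_pembrolizumab_mg", "cost_cisplatin_mg", "cost_pemetrexed_mg",
    "cost_gemcitabine_mg", "cost_radiotherapy_event", "cost_surgery_event",
    "cost_infusion_first_hr", "cost_infusion_addl_hr",
    "cost_infusion_subseq_hr", "cost_bsc", "cost_end_of_life",
    "cost_follow_up", "cost_sae_anemia", "cost_sae_neutropenia",
    "cost_sae_thrombocytopenia", "utility_radiotherapy", "utility_surgery",
    "utility_pd", "utility_pf", "disutility_anemia", "disutility_neutropenia",
    "disutility_thrombocytopenia", "risk_anemia_pem", "risk_neutropenia_pem",
    "risk_thrombocytopenia_pem", "risk_anemia_placebo",
    "risk_neutropenia_placebo", "risk_thrombocytopenia_placebo",
    "prop_local_therapy_pem", "prop_local_therapy_placebo",
    "prop_adjuvant_uptake", "prop_surgery_among_local", "prop_nonsquamous")
}

#' Load a parameter table from CSV
#'
#' CSV dialect: comma-separated, header
#' \code{name,base,low,high,psa_class,units}, UTF-8, decimal point.
#' All mandatory parameter names must be present (missing names are an
#' error); unknown extra names are kept with a warning.
#'
#' @param path CSV file path.
#' @return a validated \code{\link{param_table}}.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.mandatory_params(), df$name)
  if (length(missing))
    stop("mandatory parameter(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  extra <- setdiff(df$name, .mandatory_params())
  if (length(extra))
    warning("unknown parameter name(s) kept: ", paste(extra, collapse = ", "))
  param_table(df)
}

#' @rdname load_parameters
#' @param pt a \code{param_table}.
#' @export
write_parameters <- function(pt, path) {
  utils::write.csv(pt$params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fill default sensitivity ranges
#'
#' Any parameter lacking explicit bounds receives the conventional
#' deterministic-sensitivity spread: \eqn{\pm 25\%} for costs, proportions
#' and anthropometrics, \eqn{\pm 10\%} for utilities and disutilities, and
#' the fixed interval [0, 0.08] for the annual discount rate.  Idempotent;
#' probabilities are capped at 1.
#'
#' @param pt a \code{param_table}.
#' @return the table with low/high completed.
#' @export
default_ranges <- function(pt) {
  df <- pt$params
  for (i in seq_len(nrow(df))) {
    if (!is.na(df$low[i]) && !is.na(df$high[i])) next
    nm <- df$name[i]; b <- df$base[i]
    if (nm == "discount_rate") {
      df$low[i] <- 0; df$high[i] <- 0.08
    } else if (grepl("^(utility_|disutility_)", nm)) {
      df$low[i] <- 0.9 * b; df$high[i] <- min(1, 1.1 * b)
    } else if (df$psa_class[i] == "fixed") {
      df$low[i] <- b; df$high[i] <- b
    } else {
      df$low[i] <- 0.75 * b
      df$high[i] <- 1.25 * b
      if (grepl("^(risk_|prop_|p_)", nm)) df$high[i] <- min(1, df$high[i])
    }
  }
  pt$params <- df
  pt
}

#' Packaged base-case parameter table
#'
#' The base-case inputs shipped with the package: Medicare/CPT-anchored
#' unit costs, published state utilities and adverse-event disutilities,
#' trial adverse-event risks, cohort anthropometrics (65 years, 70 kg,
#' 1.86 m2 BSA) and treatment-pathway proportions.
#'
#' @return a \code{\link{param_table}}.
#' @export
table1_fixture <- function() {
  load_parameters(system.file("extdata", "table1.csv", package = "periopCEA",
                              mustWork = TRUE))
}

#' Load / access parametric survival specifications
#'
#' The base case drives each arm with fitted extrapolation models:
#' log-normal OS and generalized-gamma EFS for the pembrolizumab arm,
#' Weibull OS and generalized-gamma EFS for the comparator.
#'
#' @param path JSON file with per-arm \code{os}/\code{efs} blocks, each a
#'   \code{family} + \code{params} object.
#' @return nested list of \code{\link{surv_spec}} objects:
#'   \code{$pembrolizumab$os}, \code{$pembrolizumab$efs}, \code{$placebo$os},
#'   \code{$placebo$efs}.
#' @export
load_survival_specs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(arm)
    lapply(arm, function(sp)
      do.call(surv_spec, c(list(sp$family), as.list(sp$params)))))
}

#' @rdname load_survival_specs
#' @export
base_survival_specs <- function() {
  load_survival_specs(system.file("extdata", "survival_specs.json",
                                  package = "periopCEA", mustWork = TRUE))
}

#' Chemotherapy regimen description
#'
#' Doses follow the trial protocol: pembrolizumab 200 mg flat every 21
#' days; cisplatin 75 mg/m2 day 1; partner agent pemetrexed 500 mg/m2 day
#' 1 (nonsquamous) or gemcitabine 1000 mg/m2 days 1 and 8 (squamous).
#'
#' @param pembrolizumab_mg flat dose per administration.
#' @param cisplatin_mg_m2,pemetrexed_mg_m2,gemcitabine_mg_m2 doses per m2.
#' @param gemcitabine_admin_per_cycle gemcitabine administrations per cycle.
#' @return list of class \code{"regimen"}.
#' @export
regimen <- function(pembrolizumab_mg = 200, cisplatin_mg_m2 = 75,
                    pemetrexed_mg_m2 = 500, gemcitabine_mg_m2 = 1000,
                    gemcitabine_admin_per_cycle = 2) {
  doses <- c(pembrolizumab_mg, cisplatin_mg_m2, pemetrexed_mg_m2,
             gemcitabine_mg_m2)
  if (any(doses < 0)) stop("doses must be nonnegative")
  structure(list(pembrolizumab_mg = pembrolizumab_mg,
                 cisplatin_mg_m2 = cisplatin_mg_m2,
                 pemetrexed_mg_m2 = pemetrexed_mg_m2,
                 gemcitabine_mg_m2 = gemcitabine_mg_m2,
                 gemcitabine_admin_per_cycle = gemcitabine_admin_per_cycle),
            class = "regimen")
}
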