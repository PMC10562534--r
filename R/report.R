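#' Structured reports for the whole pipeline
#'
#' Reporting wrappers around the analysis functions that write
#' deterministic CSV/JSON artifacts: the base-case incremental table, the
#' tornado, the PSA samples with the acceptability curve, or all of them.
#' Every JSON report embeds the fully resolved parameter set, a content
#' hash of it, the seed and the package version, so a result file is
#' auditable on its own.
#'
#' @param pt parameter table.
#' @param out_dir output directory (created if needed).
#' @param surv_specs per-arm survival specs.
#' @param ... passed to \code{\link{run_cea}}.
#' @return \code{run_basecase}: the \code{ce_result} (invisibly for the
#'   writers); file paths in attribute \code{"files"}.
#' @export
run_basecase <- function(pt = table1_fixture(), out_dir = NULL,
                         surv_specs = base_survival_specs(), ...) {
  res <- run_cea(pt, surv_specs, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, "basecase.json")
    jsonlite::write_json(c(.report_meta(pt), list(
      arms = stats::setNames(lapply(list(res$intervention, res$comparator),
        function(a) list(cost = a$total_cost, qaly = a$total_qaly,
                         life_years = a$life_years,
                         breakdown = as.list(a$breakdown))), res$arms),
      incremental = list(delta_cost = res$delta_cost,
                         delta_qaly = res$delta_qaly, icer = res$icer,
                         nmb = res$nmb, wtp = res$wtp,
                         dominance = res$dominance))),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(res, "files") <- path
  }
  res
}

#' @rdname run_basecase
#' @export
run_dsa <- function(pt = table1_fixture(), out_dir = NULL, ...) {
  tor <- one_way(pt, runner = function(p) run_cea(p, ...))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, "tornado.csv")
    utils::write.csv(as.data.frame(tor), path, row.names = FALSE)
    attr(tor, "files") <- path
  }
  tor
}

#' @rdname run_basecase
#' @param n,seed,wtp PSA settings (see \code{\link{run_psa}}).
#' @export
run_psa_report <- function(pt = table1_fixture(), out_dir = NULL, n = 1000,
                           seed = 1, wtp = 150000, ...) {
  psa <- run_psa(pt, n = n, seed = seed, wtp = wtp,
                 runner = function(p) run_cea(p, ...))
  cc <- ceac(psa)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "psa_samples.csv")
    f2 <- file.path(out_dir, "ceac.csv")
    f3 <- file.path(out_dir, "psa_summary.json")
    utils::write.csv(psa$samples, f1, row.names = FALSE)
    utils::write.csv(cc, f2, row.names = FALSE)
    jsonlite::write_json(c(.report_meta(pt), list(
      n = psa$n, seed = psa$seed, wtp = psa$wtp, prob_ce = psa$prob_ce,
      icer_range = psa$summary$icer_range)),
      f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(psa, "files") <- c(f1, f2, f3)
  }
  psa
}

#' @rdname run_basecase
#' @export
run_all <- function(pt = table1_fixture(), out_dir = "periopCEA-report",
                    n = 1000, seed = 1, ...) {
  list(basecase = run_basecase(pt, out_dir, ...),
       dsa = run_dsa(pt, out_dir, ...),
       psa = run_psa_report(pt, out_dir, n = n, seed = seed, ...))
}

# 32-bit FNV-1a content hash in double arithmetic (exact below 2^53)
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b)) +
      (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.report_meta <- function(pt) {
  df <- pt$params
  list(package = "periopCEA",
       version = as.character(utils::packageVersion("periopCEA")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config_hash = .fnv1a(paste(df$name, df$base, collapse = ";")),
       parameters = stats::setNames(as.list(df$base), df$name))
}
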