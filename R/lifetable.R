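#' Background mortality table (synthetic US-like period life table)
#'
#' Annual probabilities of death by single year of age from 65 upward,
#' generated from a Gompertz law \eqn{q(a) = B e^{Ca}} anchored to recent
#' United States all-cause period mortality for both sexes combined
#' (q(65) about 1.3\%, q(75) about 3.4\%, q(85) about 9.3\%).  This is a
#' synthetic stand-in for an official life table, used only as a floor on
#' the model's death probability so that extrapolated trial survival can
#' never imply lower mortality than the general population.
#'
#' @param max_age last age tabulated.
#' @param B,C Gompertz coefficients.
#' @return data.frame with columns \code{age}, \code{qx}.
#' @export
background_mortality_table <- function(max_age = 110, B = 2.17e-5,
                                       C = 0.0984) {
  age <- 65:max_age
  data.frame(age = age, qx = pmin(1, B * exp(C * age)))
}

# annual death probability at (integer) attained age, clamped to the table
.bg_qx <- function(tab, age) {
  i <- pmin(pmax(floor(age) - tab$age[1] + 1, 1), nrow(tab))
  tab$qx[i]
}
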