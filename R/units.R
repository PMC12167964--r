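# Molar masses (g mol^-1). CO2SYS-conventional values; intermediates are never
# rounded, only final reported figures.
M_C <- 12.011
M_CACO3 <- 100.0869
M_CO2 <- 44.009

#' Convert global carbonate production from TgC to PgCaCO3
#'
#' Reef carbonate budgets are quoted either as teragrams of carbon fixed into
#' CaCO3 per year or as petagrams of mineral CaCO3 per year. One mole of
#' carbon corresponds to one mole of CaCO3, so the conversion is the ratio of
#' molar masses (100.0869 / 12.011) with a Tg-to-Pg factor of 1000.
#'
#' @param tgc Numeric vector, carbonate production in TgC per year (>= 0).
#' @return Numeric vector, production in PgCaCO3 per year.
#' @examples
#' tgc_to_pgcaco3(c(30, 150, 300)) # ~0.25, 1.25, 2.50
#' @export
tgc_to_pgcaco3 <- function(tgc) {
  stopifnot(is.numeric(tgc), all(tgc >= 0))
  tgc * (M_CACO3 / M_C) / 1000
}

#' Convert a carbon mass from PgC to GtCO2
#'
#' Carbon budget statements are conventionally expressed in Gt of CO2;
#' 1 PgC = 44.009/12.011 = 3.664 GtCO2.
#'
#' @param pgc Numeric vector in PgC.
#' @return Numeric vector in GtCO2.
#' @examples
#' pgc_to_gtco2(1) # 3.664
#' @export
pgc_to_gtco2 <- function(pgc) {
  stopifnot(is.numeric(pgc))
  pgc * (M_CO2 / M_C)
}
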