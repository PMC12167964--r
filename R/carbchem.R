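# Seawater carbonate-system equilibrium solver, total pH scale.
#
# Constants dialect (one documented set, versioned here):
#   K0  Weiss (1974)            CO2 solubility, mol kg-1 atm-1
#   K1, K2  Lueker et al. (2000)  carbonic acid, total scale
#   KB  Dickson (1990)          boric acid, total scale
#   KW  Millero (1995)          water, total scale
#   TB  Uppstrom (1974)         total boron from salinity
# Nutrient (silicate/phosphate) alkalinity is excluded: the box model carries
# no nutrient state. Fugacity correction is neglected (pCO2 = [CO2*]/K0).
# Internal concentrations are mol kg-1; the user-facing interface accepts
# umol kg-1 (default) or mol m-3 via a fixed reference density of 1025 kg m-3.

RHO_SW <- 1025 # kg m-3, reference density for mol m-3 <-> mol kg-1

#' Equilibrium constants for the seawater carbonate system
#'
#' @param temperature Temperature, degrees C (-2 to 40).
#' @param salinity Practical salinity (20 to 42).
#' @return A list of numeric vectors: `K0` (mol kg-1 atm-1), `K1`, `K2`,
#'   `KB`, `KW` (total scale, mol kg-1), and total boron `TB` (mol kg-1).
#' @export
carb_constants <- function(temperature, salinity) {
  stopifnot(all(temperature >= -2 & temperature <= 40),
    all(salinity >= 20 & salinity <= 42))
  TK <- temperature + 273.15
  S <- salinity
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)
  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * log(TK) -
    0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.9290 - 3.16967 * log(TK) -
    0.01781 * S + 0.0001122 * S^2
  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S +
    1.728 * S^1.5 - 0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S -
    (24.4344 + 25.085 * sqrt(S) + 0.2474 * S) * log(TK) +
    0.053105 * sqrt(S) * TK
  lnKW <- 148.9652 - 13847.26 / TK - 23.6521 * log(TK) +
    (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqrt(S) - 0.01615 * S
  list(
    K0 = exp(lnK0), K1 = 10^(-pK1), K2 = 10^(-pK2),
    KB = exp(lnKB), KW = exp(lnKW),
    TB = 0.000416 * S / 35
  )
}

# Total alkalinity residual (mol kg-1) and its d/dh, at [H+] = h, for DIC in
# mol kg-1. Carbonate + borate + water terms.
.alk_residual <- function(h, dic, alk, K) {
  denom <- h * h + K$K1 * h + K$K1 * K$K2
  ca <- dic * K$K1 * (h + 2 * K$K2) / denom
  ca + K$TB * K$KB / (K$KB + h) + K$KW / h - h - alk
}

.alk_residual_deriv <- function(h, dic, K) {
  denom <- h * h + K$K1 * h + K$K1 * K$K2
  dca <- dic * K$K1 * (denom - (h + 2 * K$K2) * (2 * h + K$K1)) / denom^2
  dca - K$TB * K$KB / (K$KB + h)^2 - K$KW / h^2 - 1
}

# Vectorised safeguarded Newton on [H+] over pH in [2, 12]; warm-startable.
# The residual is strictly decreasing in h, so a sign-based bracket update is
# valid everywhere.
.ph_solve <- function(dic, alk, K, ph_init = NULL) {
  n <- max(length(dic), length(alk))
  dic <- rep_len(dic, n)
  alk <- rep_len(alk, n)
  h_lo <- rep(10^-12, n)
  h_hi <- rep(10^-2, n)
  r_lo <- .alk_residual(h_lo, dic, alk, K)
  r_hi <- .alk_residual(h_hi, dic, alk, K)
  if (any(r_lo < 0 | r_hi > 0)) {
    stop(sprintf(
      "chemistry solver failure: no pH root in [2, 12] (first bad input: DIC=%g, Alk=%g mol/kg)",
      dic[which(r_lo < 0 | r_hi > 0)[1]], alk[which(r_lo < 0 | r_hi > 0)[1]]),
      call. = FALSE)
  }
  h <- if (is.null(ph_init)) sqrt(h_lo * h_hi) else rep_len(10^(-ph_init), n)
  for (i in seq_len(100)) {
    r <- .alk_residual(h, dic, alk, K)
    pos <- r > 0
    h_lo[pos] <- h[pos]
    h_hi[!pos] <- h[!pos]
    if (all(abs(r) < 1e-15)) break
    step <- r / .alk_residual_deriv(h, dic, K)
    h_new <- h - step
    bad <- !(h_new > h_lo & h_new < h_hi) | !is.finite(h_new)
    h_new[bad] <- sqrt(h_lo[bad] * h_hi[bad]) # bisect in log space
    h <- h_new
  }
  h
}

.check_conditions <- function(temperature, salinity) {
  if (any(temperature < -2 | temperature > 40)) {
    stop("temperature out of range [-2, 40] degC", call. = FALSE)
  }
  if (any(salinity < 20 | salinity > 42)) {
    stop("salinity out of range [20, 42]", call. = FALSE)
  }
}

.to_molkg <- function(x, units) {
  switch(units, umol_kg = x * 1e-6, mol_m3 = x / RHO_SW,
    stop("units must be 'umol_kg' or 'mol_m3'", call. = FALSE))
}

#' Solve the seawater carbonate system from DIC and alkalinity
#'
#' Given dissolved inorganic carbon, total alkalinity, temperature and
#' salinity, finds the pH (total scale) at which the alkalinity balance
#' (carbonate + borate + water) closes, and returns the full speciation,
#' pCO2 and the Revelle (buffer) factor. This is the chemistry through which
#' a 2:1 alkalinity:DIC addition from declining reef calcification lowers
#' seawater pCO2 and draws down atmospheric CO2.
#'
#' @param dic,alk DIC and total alkalinity, in `units` (vectorised).
#' @param temperature Temperature, degC. Default 25.
#' @param salinity Practical salinity. Default 35.
#' @param units `"umol_kg"` (default) or `"mol_m3"` (converted with a fixed
#'   density of 1025 kg m-3).
#' @param revelle Compute the Revelle factor by central finite difference
#'   (two extra solves)? Default TRUE.
#' @return A tibble with columns `dic`, `alk`, `temperature`, `salinity`,
#'   `ph` (total scale), `pco2_uatm`, `co2`, `hco3`, `co3` (same units as the
#'   inputs) and `revelle`.
#' @examples
#' solve_carb(2000, 2300, temperature = 25, salinity = 35)
#' @export
solve_carb <- function(dic, alk, temperature = 25, salinity = 35,
                       units = "umol_kg", revelle = TRUE) {
  stopifnot(all(dic > 0), all(alk > 0))
  .check_conditions(temperature, salinity)
  n <- max(length(dic), length(alk), length(temperature), length(salinity))
  dic <- rep_len(dic, n); alk <- rep_len(alk, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  K <- carb_constants(temperature, salinity)
  dic_kg <- .to_molkg(dic, units)
  alk_kg <- .to_molkg(alk, units)
  h <- .ph_solve(dic_kg, alk_kg, K)
  denom <- h * h + K$K1 * h + K$K1 * K$K2
  co2 <- dic_kg * h * h / denom
  hco3 <- dic_kg * K$K1 * h / denom
  co3 <- dic_kg * K$K1 * K$K2 / denom
  pco2 <- co2 / K$K0 * 1e6
  back <- switch(units, umol_kg = 1e6, mol_m3 = RHO_SW)
  rev_fac <- rep(NA_real_, n)
  if (revelle) {
    d <- 1e-4 * dic_kg
    p_hi <- .pco2_of(dic_kg + d, alk_kg, K)
    p_lo <- .pco2_of(dic_kg - d, alk_kg, K)
    rev_fac <- (p_hi - p_lo) / (2 * d) * dic_kg / pco2
  }
  tibble::tibble(
    dic = dic, alk = alk, temperature = temperature, salinity = salinity,
    ph = -log10(h), pco2_uatm = pco2,
    co2 = co2 * back, hco3 = hco3 * back, co3 = co3 * back,
    revelle = rev_fac
  )
}

# pCO2 (uatm) from DIC/Alk in mol kg-1 with precomputed constants; core of
# the box-model inner loop.
.pco2_of <- function(dic_kg, alk_kg, K, ph_init = NULL) {
  h <- .ph_solve(dic_kg, alk_kg, K, ph_init = ph_init)
  co2 <- dic_kg * h * h / (h * h + K$K1 * h + K$K1 * K$K2)
  co2 / K$K0 * 1e6
}

#' DIC at a prescribed pCO2 and alkalinity
#'
#' Inverse of [solve_carb()] in the pCO2 direction: finds the unique DIC at
#' which seawater of the given alkalinity has the target pCO2. Used to
#' initialise the preindustrial surface ocean at gas-exchange equilibrium
#' with the atmosphere. With [CO2*] fixed by K0 * pCO2, the alkalinity
#' balance is again a one-dimensional root problem in pH.
#'
#' @param pco2 Target pCO2, uatm (> 0, vectorised).
#' @param alk Total alkalinity in `units`.
#' @inheritParams solve_carb
#' @return DIC in `units`, same length as the broadcast inputs.
#' @examples
#' dic_from_pco2(280, 2300)
#' @export
dic_from_pco2 <- function(pco2, alk, temperature = 25, salinity = 35,
                          units = "umol_kg") {
  stopifnot(all(pco2 > 0), all(alk > 0))
  .check_conditions(temperature, salinity)
  n <- max(length(pco2), length(alk), length(temperature), length(salinity))
  pco2 <- rep_len(pco2, n); alk <- rep_len(alk, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  K <- carb_constants(temperature, salinity)
  alk_kg <- .to_molkg(alk, units)
  co2 <- K$K0 * pco2 * 1e-6
  # residual strictly decreasing in h as before
  res <- function(h) {
    K$K1 * co2 / h + 2 * K$K1 * K$K2 * co2 / h^2 +
      K$TB * K$KB / (K$KB + h) + K$KW / h - h - alk_kg
  }
  h_lo <- rep(10^-12, n); h_hi <- rep(10^-2, n)
  if (any(res(h_lo) < 0 | res(h_hi) > 0)) {
    stop("chemistry solver failure: no pH root in [2, 12] for dic_from_pco2",
      call. = FALSE)
  }
  for (i in seq_len(200)) {
    h <- sqrt(h_lo * h_hi)
    r <- res(h)
    pos <- r > 0
    h_lo[pos] <- h[pos]
    h_hi[!pos] <- h[!pos]
    if (max(abs(h_hi - h_lo) / h_lo) < 1e-14) break
  }
  h <- sqrt(h_lo * h_hi)
  dic_kg <- co2 * (1 + K$K1 / h + K$K1 * K$K2 / h^2)
  back <- switch(units, umol_kg = 1e6, mol_m3 = RHO_SW)
  dic_kg * back
}

#' Sensitivity of seawater pCO2 to DIC and alkalinity perturbations
#'
#' Central finite-difference diagnostics of the surface-ocean buffer state:
#' the Revelle factor (fractional pCO2 change per fractional DIC change at
#' fixed alkalinity) and the partial derivatives of pCO2 with respect to
#' alkalinity and DIC. The net effect of a 2:1 Alk:DIC addition,
#' 2*dpCO2/dAlk + dpCO2/dDIC, is negative in realistic surface water — the
#' sign of the reef feedback.
#'
#' @inheritParams solve_carb
#' @param step Relative finite-difference step (default 1e-4 of each input).
#' @return A tibble with columns `revelle`, `dpco2_dalk`, `dpco2_ddic`
#'   (uatm per unit of `units`), and `net_2to1` = 2*dpco2_dalk + dpco2_ddic.
#' @export
uptake_efficiency <- function(dic, alk, temperature = 25, salinity = 35,
                              units = "umol_kg", step = 1e-4) {
  stopifnot(all(dic > 0), all(alk > 0))
  .check_conditions(temperature, salinity)
  n <- max(length(dic), length(alk), length(temperature), length(salinity))
  dic <- rep_len(dic, n); alk <- rep_len(alk, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  K <- carb_constants(temperature, salinity)
  dic_kg <- .to_molkg(dic, units)
  alk_kg <- .to_molkg(alk, units)
  dd <- step * dic_kg
  da <- step * alk_kg
  p0 <- .pco2_of(dic_kg, alk_kg, K)
  dp_ddic <- (.pco2_of(dic_kg + dd, alk_kg, K) -
    .pco2_of(dic_kg - dd, alk_kg, K)) / (2 * dd)
  dp_dalk <- (.pco2_of(dic_kg, alk_kg + da, K) -
    .pco2_of(dic_kg, alk_kg - da, K)) / (2 * da)
  per_unit <- switch(units, umol_kg = 1e-6, mol_m3 = 1 / RHO_SW)
  tibble::tibble(
    revelle = dp_ddic * dic_kg / p0,
    dpco2_dalk = dp_dalk * per_unit,
    dpco2_ddic = dp_ddic * per_unit,
    net_2to1 = (2 * dp_dalk + dp_ddic) * per_unit
  )
}
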