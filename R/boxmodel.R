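# Reduced-complexity transient ocean carbon cycle: four boxes (reef-shelf
# surface, open tropical surface, high-latitude surface, deep), prescribed
# atmospheric CO2, constant piston velocity gas exchange, volume-conserving
# overturning + mixing transport, reef alkalinity/DIC injection into the
# reef-shelf box. Explicit Euler time stepping.

SECONDS_PER_YEAR <- 365.25 * 86400
SV_TO_M3_YR <- 1e6 * SECONDS_PER_YEAR
.box_names <- c("reef", "trop", "high", "deep")

# Prescribed linear SST warming ramps (degC per century from 2005, applied to
# surface boxes, held constant after a stabilisation year). Magnitudes are
# standard scenario surface-warming scales.
.warming_table <- list(
  rcp26 = c(rate = 1.0, stab = 2100),
  rcp45 = c(rate = 1.8, stab = 2150),
  rcp85 = c(rate = 3.5, stab = 2250)
)

.warming_delta <- function(rcp, year) {
  if (is.null(rcp)) return(0)
  w <- .warming_table[[rcp]]
  w[["rate"]] * pmin(pmax(year - 2005, 0), w[["stab"]] - 2005) / 100
}

#' Configure the four-box ocean
#'
#' Builds the geometry, transport operator and exchange parameters of the
#' reduced ocean: a small reef-shelf surface box (where reef fluxes enter),
#' an open tropical surface box, a high-latitude surface box, and a deep
#' reservoir. Overturning follows high-latitude sinking (high -> deep ->
#' tropical -> high); bidirectional mixing connects reef-trop, trop-deep and
#' high-deep. Transport is volume-conserving by construction.
#'
#' @param total_area Ocean surface area, m2.
#' @param total_volume Ocean volume, m3.
#' @param surface_depth Surface box depth, m.
#' @param area_frac Named fractions of surface area for `reef`, `trop`,
#'   `high` (must sum to 1; reef fraction <= 0.02).
#' @param temperature Named base temperatures (degC) for the four boxes.
#' @param salinity Practical salinity (single value, all boxes).
#' @param alk0 Uniform preindustrial alkalinity, mol m-3.
#' @param piston_velocity Gas-transfer (piston) velocity, m d-1, constant.
#' @param overturning Overturning rate, Sv.
#' @param mixing Named bidirectional mixing rates, Sv: `reef_trop`,
#'   `trop_deep`, `high_deep`.
#' @param dt Time step, years (<= 0.1 for stability).
#' @param warming Apply the per-RCP linear SST ramp in scenario runs?
#' @return A `box_config` list with areas, volumes (m3), the transport
#'   operator `L` (y-1, acting on concentrations), and all parameters.
#' @export
box_config <- function(total_area = 3.61e14, total_volume = 1.335e18,
                       surface_depth = 100,
                       area_frac = c(reef = 0.01, trop = 0.75, high = 0.24),
                       temperature = c(reef = 27, trop = 24, high = 4, deep = 3),
                       salinity = 35, alk0 = 2.40,
                       piston_velocity = 4,
                       overturning = 22,
                       mixing = c(reef_trop = 10, trop_deep = 30, high_deep = 60),
                       dt = 0.05, warming = TRUE) {
  stopifnot(total_area > 0, total_volume > 0, surface_depth > 0,
    all(area_frac > 0), abs(sum(area_frac) - 1) < 1e-12,
    piston_velocity >= 0, overturning >= 0, all(mixing >= 0),
    dt > 0, dt <= 0.1)
  if (area_frac[["reef"]] > 0.02) {
    stop("reef-shelf box area fraction must be <= 2% of the ocean surface",
      call. = FALSE)
  }
  area <- c(area_frac[["reef"]], area_frac[["trop"]], area_frac[["high"]], 0) *
    total_area
  vol <- area * surface_depth
  vol[4] <- total_volume - sum(vol[1:3])
  stopifnot(vol[4] > 0)
  names(area) <- names(vol) <- .box_names

  # Flow matrix Q[i, j] = water flux i -> j (m3 y-1).
  Q <- matrix(0, 4, 4, dimnames = list(.box_names, .box_names))
  psi <- overturning * SV_TO_M3_YR
  Q["high", "deep"] <- Q["high", "deep"] + psi
  Q["deep", "trop"] <- Q["deep", "trop"] + psi
  Q["trop", "high"] <- Q["trop", "high"] + psi
  mix <- function(a, b, sv) {
    m <- sv * SV_TO_M3_YR
    Q[a, b] <<- Q[a, b] + m
    Q[b, a] <<- Q[b, a] + m
  }
  mix("reef", "trop", mixing[["reef_trop"]])
  mix("trop", "deep", mixing[["trop_deep"]])
  mix("high", "deep", mixing[["high_deep"]])

  # Concentration tendency operator: (L %*% C)_i = (sum_j Q[j,i] C_j -
  # C_i sum_j Q[i,j]) / V_i. Row sums of (Q - diag(outflow)) are zero, so
  # volume-weighted totals are conserved exactly.
  L <- t(Q) / vol
  diag(L) <- diag(L) - rowSums(Q) / vol

  structure(list(
    area = area, volume = vol, temperature = temperature,
    salinity = salinity, alk0 = alk0,
    piston_velocity = piston_velocity, overturning = overturning,
    mixing = mixing, Q = Q, L = L, dt = dt, warming = warming,
    total_area = total_area, total_volume = total_volume
  ), class = "box_config")
}

#' @export
print.box_config <- function(x, ...) {
  cat("<box_config> 4-box ocean\n")
  cat(sprintf("  volumes (m3): %s\n",
    paste(sprintf("%s=%.3g", .box_names, x$volume), collapse = ", ")))
  cat(sprintf("  overturning %g Sv; piston velocity %g m/d; dt %g y\n",
    x$overturning, x$piston_velocity, x$dt))
  invisible(x)
}

# Instantaneous DIC tendency (mol m-3 y-1) and per-box air-sea flux (mol y-1)
# for given per-box DIC/Alk (mol m-3), surface temperatures and atmospheric
# pCO2. Gas exchange: F = kw * K0 * (pCO2_atm - pCO2_box) * area, applied to
# the three surface boxes; the deep box exchanges nothing.
.box_fluxes <- function(dic, alk, config, pco2_atm, temps_surf, ph_init = NULL) {
  K <- carb_constants(temps_surf, config$salinity)
  dic_kg <- dic[1:3] / RHO_SW
  alk_kg <- alk[1:3] / RHO_SW
  h <- .ph_solve(dic_kg, alk_kg, K, ph_init = ph_init)
  co2 <- dic_kg * h * h / (h * h + K$K1 * h + K$K1 * K$K2)
  pco2 <- co2 / K$K0 * 1e6
  kw <- config$piston_velocity * 365.25 # m y-1
  # K0 mol kg-1 atm-1 * rho -> mol m-3 atm-1; /1e6 per uatm
  f_surf <- kw * K$K0 * RHO_SW * 1e-6 * (pco2_atm - pco2) * config$area[1:3]
  list(airsea = c(f_surf, 0), pco2 = pco2, ph = -log10(h))
}

#' Initialise the preindustrial stationary ocean
#'
#' Sets alkalinity uniform at its preindustrial value and solves for the
#' four-box DIC distribution at which transport and air-sea exchange balance
#' exactly in every box under the preindustrial atmosphere. Individual
#' surface boxes carry non-zero fluxes (outgassing or uptake balanced by
#' circulation, as in the real preindustrial ocean); the global flux is zero,
#' so an unforced control run is drift-free.
#'
#' @param config A [box_config()].
#' @param pco2_atm Preindustrial atmospheric CO2, uatm (~ ppm). Default 284.7.
#' @return A `box_state` list: `dic`, `alk` (mol m-3, length 4), `ph`
#'   (surface), `year` = NA until used in a run.
#' @export
init_preindustrial <- function(config, pco2_atm = 284.7) {
  stopifnot(inherits(config, "box_config"), pco2_atm > 0)
  alk <- rep(config$alk0, 4)
  t_surf <- config$temperature[1:3]
  dic_surf <- dic_from_pco2(pco2_atm, config$alk0, temperature = t_surf,
    salinity = config$salinity, units = "mol_m3")
  x0 <- c(dic_surf, dic_surf[2] + 0.15)
  tendency <- function(x) {
    fl <- .box_fluxes(x, alk, config, pco2_atm, t_surf)
    as.numeric(config$L %*% x) + fl$airsea / config$volume
  }
  sol <- pracma::fsolve(tendency, x0, tol = 1e-14)
  dic <- sol$x
  resid <- max(abs(tendency(dic)))
  if (!all(is.finite(dic)) || resid > 1e-10) {
    stop("preindustrial spin-up failed to converge to a stationary state",
      call. = FALSE)
  }
  fl <- .box_fluxes(dic, alk, config, pco2_atm, t_surf)
  structure(list(
    dic = setNames(dic, .box_names), alk = setNames(alk, .box_names),
    ph = fl$ph, pco2_atm = pco2_atm, year = NA_real_
  ), class = "box_state")
}

#' Advance the box ocean by one explicit Euler step
#'
#' Applies transport, air-sea exchange and the reef alkalinity/DIC injection
#' (wholly into the reef-shelf box) over `dt` years. DIC and alkalinity are
#' advected identically; gas exchange touches only DIC.
#'
#' @param state A `box_state`.
#' @param config A [box_config()].
#' @param pco2_atm Atmospheric CO2 during the step, uatm.
#' @param reef_alk,reef_dic Reef-derived global sources, Pmol y-1.
#' @param dt Time step, years (<= 0.1).
#' @param temps_surf Optional surface temperatures (degC) overriding the
#'   configured base values (used for warming ramps).
#' @return The updated `box_state`, with attributes `airsea` (per-box mol
#'   absorbed during the step) and `pco2` (surface pCO2, uatm).
#' @export
step_box <- function(state, config, pco2_atm, reef_alk = 0, reef_dic = 0,
                     dt = config$dt, temps_surf = config$temperature[1:3]) {
  stopifnot(inherits(state, "box_state"), dt > 0, dt <= 0.1)
  fl <- .box_fluxes(state$dic, state$alk, config, pco2_atm, temps_surf,
    ph_init = state$ph)
  inject_dic <- c(reef_dic * 1e15 / config$volume[[1]], 0, 0, 0)
  inject_alk <- c(reef_alk * 1e15 / config$volume[[1]], 0, 0, 0)
  dic <- state$dic +
    (as.numeric(config$L %*% state$dic) + fl$airsea / config$volume +
      inject_dic) * dt
  alk <- state$alk +
    (as.numeric(config$L %*% state$alk) + inject_alk) * dt
  if (any(dic <= 0) || any(alk <= 0)) {
    bad <- .box_names[which(dic <= 0 | alk <= 0)[1]]
    stop(sprintf("unstable timestep: negative concentration in box '%s'", bad),
      call. = FALSE)
  }
  out <- structure(list(
    dic = setNames(dic, .box_names), alk = setNames(alk, .box_names),
    ph = fl$ph, pco2_atm = pco2_atm,
    year = if (is.na(state$year)) NA_real_ else state$year + dt
  ), class = "box_state")
  attr(out, "airsea") <- fl$airsea * dt
  attr(out, "pco2") <- fl$pco2
  out
}

#' Integrate the box ocean over a CO2 pathway
#'
#' Runs the transient simulation: annual prescribed atmospheric CO2, optional
#' reef alkalinity/DIC boundary fluxes (a [build_scenario()] table), optional
#' per-RCP SST warming ramp. The historical segment of a scenario run is
#' bitwise identical to its reference run (same code path, zero reef flux
#' before 2005). Diagnostics are annual means.
#'
#' @param config A [box_config()].
#' @param pathway A tibble with columns `year`, `co2_ppm` covering `years`
#'   (see [rcp_co2_pathway()]).
#' @param fluxes Optional `reef_fluxes` tibble from [build_scenario()];
#'   `NULL` for a reference (no-reef-flux) run.
#' @param years Years to simulate. Default: the pathway's years.
#' @param init Initial `box_state`; default [init_preindustrial()] at the
#'   first pathway year's CO2.
#' @param rcp RCP label for the warming ramp (taken from `fluxes` if absent).
#' @param control Logical; a preindustrial control run (constant first-year
#'   CO2, no warming, no reef fluxes).
#' @return A `box_run` object: tibble of annual diagnostics in `$annual`
#'   (per-box and global air-sea flux, PgC y-1; surface pCO2; per-box DIC and
#'   alkalinity, mol m-3), exact bookkeeping sums in `$bookkeeping`, the
#'   final state, and metadata.
#' @export
integrate_box <- function(config, pathway, fluxes = NULL, years = NULL,
                          init = NULL, rcp = NULL, control = FALSE) {
  stopifnot(inherits(config, "box_config"),
    is.data.frame(pathway), all(c("year", "co2_ppm") %in% names(pathway)))
  years <- if (is.null(years)) pathway$year else years
  years <- as.numeric(years)
  if (!all(years %in% pathway$year)) {
    stop("CO2 pathway does not cover all requested years", call. = FALSE)
  }
  co2 <- pathway$co2_ppm[match(years, pathway$year)]
  if (control) co2 <- rep(co2[1], length(years))
  if (is.null(rcp) && !is.null(fluxes)) rcp <- attr(fluxes, "rcp")
  # Zero-amplitude and absent flux tables take the same code path.
  reef_alk <- reef_dic <- rep(0, length(years))
  if (!is.null(fluxes)) {
    idx <- match(years, fluxes$year)
    if (anyNA(idx)) stop("flux series does not cover all years", call. = FALSE)
    reef_alk <- fluxes$alk_pmol_yr[idx]
    reef_dic <- fluxes$dic_pmol_yr[idx]
  }
  if (is.null(init)) init <- init_preindustrial(config, co2[1])
  state <- init
  state$year <- years[1]
  nstep <- max(1L, round(1 / config$dt))
  dt <- 1 / nstep
  inv0_dic <- sum(init$dic * config$volume)
  inv0_alk <- sum(init$alk * config$volume)
  cum_airsea <- 0
  cum_reef_dic <- 0
  cum_reef_alk <- 0
  n <- length(years)
  ann_flux <- matrix(0, n, 4, dimnames = list(NULL, .box_names))
  ann_pco2 <- matrix(0, n, 3, dimnames = list(NULL, .box_names[1:3]))
  dic_traj <- matrix(0, n, 4, dimnames = list(NULL, .box_names))
  alk_traj <- matrix(0, n, 4, dimnames = list(NULL, .box_names))
  warm <- config$warming && !control && !is.null(rcp)
  for (i in seq_len(n)) {
    t_surf <- config$temperature[1:3]
    if (warm) t_surf <- t_surf + .warming_delta(rcp, years[i])
    acc <- numeric(4)
    acc_p <- numeric(3)
    for (s in seq_len(nstep)) {
      state <- step_box(state, config, co2[i], reef_alk[i], reef_dic[i],
        dt = dt, temps_surf = t_surf)
      acc <- acc + attr(state, "airsea")
      acc_p <- acc_p + attr(state, "pco2")
    }
    cum_airsea <- cum_airsea + sum(acc)
    cum_reef_dic <- cum_reef_dic + reef_dic[i] * 1e15
    cum_reef_alk <- cum_reef_alk + reef_alk[i] * 1e15
    ann_flux[i, ] <- acc * M_C / 1e15 # mol over 1 y -> PgC y-1
    ann_pco2[i, ] <- acc_p / nstep
    dic_traj[i, ] <- state$dic
    alk_traj[i, ] <- state$alk
  }
  annual <- tibble::tibble(
    year = years,
    flux_reef = ann_flux[, "reef"], flux_trop = ann_flux[, "trop"],
    flux_high = ann_flux[, "high"],
    flux_global = rowSums(ann_flux),
    pco2_atm = co2,
    pco2_reef = ann_pco2[, "reef"], pco2_trop = ann_pco2[, "trop"],
    pco2_high = ann_pco2[, "high"],
    dic_reef = dic_traj[, "reef"], dic_trop = dic_traj[, "trop"],
    dic_high = dic_traj[, "high"], dic_deep = dic_traj[, "deep"],
    alk_reef = alk_traj[, "reef"], alk_trop = alk_traj[, "trop"],
    alk_high = alk_traj[, "high"], alk_deep = alk_traj[, "deep"]
  )
  structure(list(
    annual = annual,
    bookkeeping = list(
      dic_inventory_initial = inv0_dic,
      alk_inventory_initial = inv0_alk,
      dic_inventory_change = sum(state$dic * config$volume) - inv0_dic,
      alk_inventory_change = sum(state$alk * config$volume) - inv0_alk,
      cum_airsea_mol = cum_airsea,
      cum_reef_dic_mol = cum_reef_dic,
      cum_reef_alk_mol = cum_reef_alk
    ),
    state = state, config = config,
    rcp = rcp, g0 = attr(fluxes, "g0"), control = control,
    reference = is.null(fluxes) || all(reef_dic == 0)
  ), class = "box_run")
}

#' @export
print.box_run <- function(x, ...) {
  lab <- if (x$control) "preindustrial control"
    else if (x$reference) sprintf("reference (%s)", x$rcp %||% "?")
    else sprintf("scenario (%s, G0 = %g TgC/y)", x$rcp, x$g0)
  cat(sprintf("<box_run> %s, %d-%d\n", lab,
    min(x$annual$year), max(x$annual$year)))
  cat(sprintf("  global uptake at end: %.3f PgC/y\n",
    tail(x$annual$flux_global, 1)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.box_run <- function(x, ...) x$annual

#' @exportS3Method generics::glance
glance.box_run <- function(x, ...) {
  a <- x$annual
  bk <- x$bookkeeping
  tibble::tibble(
    rcp = x$rcp %||% NA_character_, g0 = x$g0 %||% NA_real_,
    control = x$control,
    flux_1995 = if (1995 %in% a$year) a$flux_global[a$year == 1995] else NA_real_,
    flux_final = tail(a$flux_global, 1),
    cum_uptake_pgc = sum(a$flux_global),
    # closure relative to the inventory change, floored at 1e-6 of the
    # initial inventory so an unforced control (change ~ 0) is well-defined
    carbon_closure = abs(bk$dic_inventory_change -
      (bk$cum_airsea_mol + bk$cum_reef_dic_mol)) /
      max(abs(bk$dic_inventory_change), 1e-6 * bk$dic_inventory_initial),
    alk_closure = abs(bk$alk_inventory_change - bk$cum_reef_alk_mol) /
      max(abs(bk$alk_inventory_change), 1e-6 * bk$alk_inventory_initial)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.box_run <- function(object, ...) {
  ggplot2::ggplot(object$annual,
    ggplot2::aes(x = .data$year, y = .data$flux_global)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = expression(Air - sea ~ flux ~ (PgC ~ y^{-1})),
      title = "Global ocean CO2 uptake")
}
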