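# Box-model tests use short simulation windows; the full-length ensemble is
# exercised by the acceptance suite.

const_pathway <- function(years, co2 = 284.7) {
  tibble::tibble(year = as.numeric(years), co2_ppm = co2)
}

test_that("transport operator conserves volume-weighted tracer totals", {
  cfg <- box_config()
  # row sums of the flow balance are zero: uniform tracer has zero tendency
  op_scale <- max(abs(diag(cfg$L)))
  expect_lt(max(abs(cfg$L %*% rep(1, 4))) / op_scale, 1e-12)
  x <- c(2.0, 2.1, 2.2, 2.15)
  expect_lt(abs(sum(cfg$volume * (cfg$L %*% x))) / sum(cfg$volume * x), 1e-16)
})

test_that("preindustrial control is stationary over 500 years", {
  cfg <- box_config()
  init <- init_preindustrial(cfg)
  run <- integrate_box(cfg, const_pathway(1:500), init = init, control = TRUE)
  expect_lt(max(abs(run$annual$flux_global)), 1e-3)
  inv_change <- abs(run$bookkeeping$dic_inventory_change) /
    sum(init$dic * cfg$volume)
  expect_lt(inv_change, 1e-4) # < 0.01 % over the control
})

test_that("an equilibrated, transport-free ocean is a fixed point", {
  cfg <- box_config(overturning = 0,
    mixing = c(reef_trop = 0, trop_deep = 0, high_deep = 0))
  dic <- dic_from_pco2(284.7, cfg$alk0, temperature = cfg$temperature,
    salinity = cfg$salinity, units = "mol_m3")
  state <- structure(list(
    dic = setNames(dic, c("reef", "trop", "high", "deep")),
    alk = setNames(rep(cfg$alk0, 4), c("reef", "trop", "high", "deep")),
    ph = NULL, pco2_atm = 284.7, year = 2000), class = "box_state")
  out <- step_box(state, cfg, pco2_atm = 284.7)
  expect_lt(max(abs(out$dic - state$dic)), 1e-10)
  expect_identical(out$alk, state$alk)
})

test_that("reef injection enters the reef box in a 2:1 ratio, sealed mass balance", {
  init <- init_preindustrial(box_config())
  # one step with reef flux (2 eps, eps)
  eps <- 1e-4 # Pmol/y DIC
  cfg0 <- box_config(overturning = 0,
    mixing = c(reef_trop = 0, trop_deep = 0, high_deep = 0),
    piston_velocity = 0)
  out <- step_box(init, cfg0, pco2_atm = 284.7, reef_alk = 2 * eps,
    reef_dic = eps, dt = 0.05)
  d_alk <- out$alk[["reef"]] - init$alk[["reef"]]
  d_dic <- out$dic[["reef"]] - init$dic[["reef"]]
  expect_equal(d_alk, 2 * d_dic, tolerance = 1e-10)
  # sealed atmosphere: global DIC gain equals the injected mass exactly
  gain <- sum((out$dic - init$dic) * cfg0$volume)
  expect_equal(gain, eps * 1e15 * 0.05, tolerance = 1e-10)
})

test_that("unstable forcing is reported with the offending box", {
  cfg <- box_config()
  init <- init_preindustrial(cfg)
  expect_error(
    step_box(init, cfg, pco2_atm = 284.7, reef_alk = -2e3, reef_dic = -1e3),
    "unstable timestep.*reef")
})

test_that("integration is deterministic and reference-equivalent", {
  cfg <- box_config()
  pw <- rcp_co2_pathway("4.5")
  init <- init_preindustrial(cfg, pw$co2_ppm[1])
  years <- 1990:2040
  r1 <- integrate_box(cfg, pw, years = years, init = init, rcp = "rcp45")
  r2 <- integrate_box(cfg, pw, years = years, init = init, rcp = "rcp45")
  expect_identical(r1$annual, r2$annual)
  # a zero-amplitude flux series reproduces the reference run bitwise
  zero_fl <- build_scenario("4.5", 150, years = years)
  zero_fl$alk_pmol_yr[] <- 0
  zero_fl$dic_pmol_yr[] <- 0
  r3 <- integrate_box(cfg, pw, fluxes = zero_fl, years = years, init = init,
    rcp = "rcp45")
  expect_identical(r1$annual, r3$annual)
})

test_that("carbon and alkalinity bookkeeping close on a forced run", {
  cfg <- box_config()
  pw <- rcp_co2_pathway("8.5")
  init <- init_preindustrial(cfg, pw$co2_ppm[1])
  fl <- build_scenario("8.5", 300, years = 1980:2100)
  run <- integrate_box(cfg, pw, fluxes = fl, years = 1980:2100, init = init,
    rcp = "rcp85")
  bk <- run$bookkeeping
  expect_lt(
    abs(bk$dic_inventory_change - (bk$cum_airsea_mol + bk$cum_reef_dic_mol)) /
      abs(bk$dic_inventory_change), 1e-9)
  expect_lt(
    abs(bk$alk_inventory_change - bk$cum_reef_alk_mol) /
      abs(bk$alk_inventory_change), 1e-9)
  g <- glance(run)
  expect_lt(g$carbon_closure, 1e-9)
  expect_lt(g$alk_closure, 1e-9)
})

test_that("stronger atmospheric forcing gives stronger uptake", {
  cfg <- box_config()
  init <- init_preindustrial(cfg)
  years <- 1850:2100
  r26 <- integrate_box(cfg, rcp_co2_pathway("2.6"), years = years,
    init = init, rcp = "rcp26")
  r85 <- integrate_box(cfg, rcp_co2_pathway("8.5"), years = years,
    init = init, rcp = "rcp85")
  in_2090s <- function(r) mean(r$annual$flux_global[r$annual$year %in% 2090:2099])
  expect_gt(in_2090s(r85), in_2090s(r26))
})

test_that("uptake enhancement is nearly linear in historical production", {
  cfg <- box_config()
  pw <- rcp_co2_pathway("4.5")
  init <- init_preindustrial(cfg, pw$co2_ppm[1])
  years <- 1990:2100
  ref <- integrate_box(cfg, pw, years = years, init = init, rcp = "rcp45")
  enh <- function(g0) {
    run <- integrate_box(cfg, pw, fluxes = build_scenario("4.5", g0),
      years = years, init = init, rcp = "rcp45")
    sum(run$annual$flux_global - ref$annual$flux_global)
  }
  expect_equal(enh(300) / enh(150), 2, tolerance = 0.1)
})

test_that("the explicit scheme is converged at the default timestep", {
  pw <- rcp_co2_pathway("4.5")
  years <- 1850:2100
  cum <- function(dt) {
    cfg <- box_config(dt = dt)
    init <- init_preindustrial(cfg, pw$co2_ppm[1])
    run <- integrate_box(cfg, pw, fluxes = build_scenario("4.5", 150),
      years = years, init = init, rcp = "rcp45")
    sum(run$annual$flux_global)
  }
  expect_lt(abs(cum(0.05) / cum(0.005) - 1), 0.005)
})

test_that("runs refuse years outside the pathway", {
  cfg <- box_config()
  pw <- const_pathway(2000:2010)
  expect_error(integrate_box(cfg, pw, years = 1995:2005), "cover")
})
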