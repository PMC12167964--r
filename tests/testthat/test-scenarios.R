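rcps <- c("2.6", "4.5", "8.5")

test_that("decay curves interpolate the published anchors exactly", {
  for (rcp in rcps) {
    anchors <- nec_anchors(rcp)
    curve <- fit_decay_curve(anchors)
    expect_true(curve$b > 0)
    expect_true(curve$k > 0)
    expect_lt(abs(curve$a + curve$b - anchors$nec[1]), 1e-9)
    expect_lt(max(abs(predict(curve, anchors$year) - anchors$nec)), 1e-6)
    expect_lt(curve$a, anchors$nec[3]) # asymptote below the last anchor
  }
})

test_that("degenerate or non-decaying anchors are refused", {
  flat <- tibble::tibble(year = c(2005, 2050, 2100), nec = c(2.8, 2.8, 2.8))
  expect_error(fit_decay_curve(flat), "unfittable")
  rising <- tibble::tibble(year = c(2005, 2050, 2100), nec = c(2.8, 3.0, 3.2))
  expect_error(fit_decay_curve(rising), "unfittable")
  negative_start <- tibble::tibble(year = c(2005, 2050, 2100),
    nec = c(-0.1, -0.5, -0.9))
  expect_error(fit_decay_curve(negative_start), "unfittable")
  two <- tibble::tibble(year = c(2005, 2050), nec = c(2.8, 0.95))
  expect_error(fit_decay_curve(two), "unfittable")
})

test_that("RCP8.5 fit agrees with a brute-force (a, k) grid scan", {
  curve <- fit_decay_curve(nec_anchors("8.5"))
  expect_gt(curve$a, -1.58)
  expect_lte(curve$a, -1.57)
  # curve is effectively at its asymptote by 2200
  expect_lt(abs(predict(curve, 2200) - curve$a), 1e-2)
  scan <- oracle_decay_gridscan(nec_anchors("8.5"),
    a_grid = seq(-1.65, -1.5, by = 5e-4),
    k_grid = seq(0.05, 0.12, by = 1e-4))
  expect_lt(abs(curve$a - scan[["a"]]), 2e-3)
  expect_lt(abs(curve$k - scan[["k"]]), 5e-4)
})

test_that("relative anomalies reproduce anchor arithmetic and grow monotonically", {
  c26 <- fit_decay_curve(nec_anchors("2.6"))
  c85 <- fit_decay_curve(nec_anchors("8.5"))
  expect_identical(relative_anomaly(c26, 2005), 0)
  expect_identical(relative_anomaly(c26, 1900), 0)
  expect_lt(abs(relative_anomaly(c26, 2100) - (2.8 - 0.73) / 2.8), 1e-9)
  expect_lt(abs(relative_anomaly(c85, 2100) - (2.8 + 1.57) / 2.8), 1e-9)
  expect_gt(relative_anomaly(c85, 2100), 1) # net dissolution exceeds 1
  for (rcp in rcps) {
    rel <- relative_anomaly(fit_decay_curve(nec_anchors(rcp)), 1850:2300)
    expect_true(all(diff(rel) >= 0))
  }
})

test_that("anomaly-to-flux conversion matches the printed global flux pairs", {
  fl <- anomaly_to_global_fluxes((2.8 - 0.73) / 2.8, 30)
  expect_equal(signif(fl$alk_pmol_yr, 1), 0.004)
  expect_equal(signif(fl$dic_pmol_yr, 1), 0.002)
  fl <- anomaly_to_global_fluxes((2.8 + 1.57) / 2.8, 300)
  expect_equal(signif(fl$alk_pmol_yr, 1), 0.08)
  expect_equal(signif(fl$dic_pmol_yr, 1), 0.04)
  zero <- anomaly_to_global_fluxes(0, 150)
  expect_identical(zero$alk_pmol_yr, 0)
  expect_identical(zero$dic_pmol_yr, 0)
  expect_error(anomaly_to_global_fluxes(-0.1, 150), "negative")
})

test_that("TgC to PgCaCO3 conversion reproduces the standard pairs", {
  expect_equal(round(tgc_to_pgcaco3(c(30, 150, 300)), 2), c(0.25, 1.25, 2.50))
  expect_identical(tgc_to_pgcaco3(0), 0)
  expect_error(tgc_to_pgcaco3(-1))
})

test_that("flux series satisfy the construction invariants", {
  for (rcp in rcps) {
    fl <- build_scenario(rcp, 150)
    # 2:1 ratio bit-for-bit
    expect_identical(fl$alk_pmol_yr, 2 * fl$dic_pmol_yr)
    expect_true(all(fl$alk_pmol_yr[fl$year < 2005] == 0))
    expect_true(all(diff(fl$alk_pmol_yr) >= 0))
    v2150 <- fl$alk_pmol_yr[fl$year == 2150]
    v2300 <- fl$alk_pmol_yr[fl$year == 2300]
    expect_lt(abs(v2300 - v2150), 0.01 * v2300)
  }
})

test_that("fluxes scale linearly in historical production", {
  for (rcp in rcps) {
    f30 <- build_scenario(rcp, 30)
    f300 <- build_scenario(rcp, 300)
    expect_equal(f300$dic_pmol_yr, 10 * f30$dic_pmol_yr, tolerance = 1e-12)
  }
})

test_that("scenario fluxes are ordered by emissions scenario", {
  f26 <- build_scenario("2.6", 150)
  f45 <- build_scenario("4.5", 150)
  f85 <- build_scenario("8.5", 150)
  sel <- f26$year >= 2010
  expect_true(all(f85$alk_pmol_yr[sel] >= f45$alk_pmol_yr[sel]))
  expect_true(all(f45$alk_pmol_yr[sel] >= f26$alk_pmol_yr[sel]))
})

test_that("most of the decline occurs before 2050", {
  for (rcp in rcps) {
    curve <- fit_decay_curve(nec_anchors(rcp))
    expect_gt(relative_anomaly(curve, 2050) / relative_anomaly(curve, 2300),
      0.75)
  }
})

test_that("scenario ratios are independent of the production rate", {
  fl <- build_scenario("4.5", 150)
  ratio <- fl$dic_pmol_yr[fl$year == 2050] / fl$dic_pmol_yr[fl$year == 2100]
  expect_equal(ratio, 1.225 / 1.496429, tolerance = 1e-4)
  expect_identical(fl$alk_pmol_yr[fl$year == 1900], 0)
})

test_that("flux tables carry metadata and plot", {
  fl <- build_scenario("2.6", 30)
  expect_s3_class(fl, "reef_fluxes")
  expect_identical(attr(fl, "rcp"), "rcp26")
  expect_identical(attr(fl, "g0"), 30)
  expect_s3_class(autoplot(fl), "ggplot")
  curve <- attr(fl, "curve")
  expect_named(tidy(curve), c("term", "estimate", "unit"))
  expect_lt(glance(curve)$max_anchor_misfit, 1e-6)
})
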