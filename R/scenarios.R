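# Reef calcification decline scenarios: exponential decay of areal net
# ecosystem calcification (NEC) anchored at 2005/2050/2100, converted to
# global alkalinity and DIC sources in a 2:1 molar ratio.

# Central published anchors: areal NEC in kgCaCO3 m-2 y-1.
.nec_anchor_table <- list(
  rcp26 = c(`2005` = 2.8, `2050` = 0.95, `2100` = 0.73),
  rcp45 = c(`2005` = 2.8, `2050` = -0.63, `2100` = -1.39),
  rcp85 = c(`2005` = 2.8, `2050` = -1.45, `2100` = -1.57)
)

.normalize_rcp <- function(rcp) {
  key <- tolower(gsub("[^0-9a-z]", "", tolower(as.character(rcp))))
  key <- sub("^rcp", "", key)
  key <- c("26" = "rcp26", "45" = "rcp45", "85" = "rcp85")[key]
  if (is.na(key)) {
    stop("unknown RCP scenario: use one of '2.6', '4.5', '8.5'", call. = FALSE)
  }
  unname(key)
}

#' Areal net ecosystem calcification anchors for an RCP
#'
#' Returns the three central projections of global-mean areal coral reef net
#' ecosystem calcification (NEC, kgCaCO3 m-2 y-1) used to anchor the decay
#' curves: the present-day (2005) central estimate of 2.8, and the projected
#' 2050 and 2100 values under the chosen Representative Concentration
#' Pathway. Negative values denote net CaCO3 dissolution.
#'
#' @param rcp One of `"2.6"`, `"4.5"`, `"8.5"` (or `"rcp26"` etc.).
#' @return A tibble with columns `year` and `nec` (kgCaCO3 m-2 y-1) and an
#'   `rcp` attribute.
#' @examples
#' nec_anchors("4.5")
#' @export
nec_anchors <- function(rcp) {
  key <- .normalize_rcp(rcp)
  v <- .nec_anchor_table[[key]]
  out <- tibble::tibble(year = as.numeric(names(v)), nec = unname(v))
  attr(out, "rcp") <- key
  out
}

#' Fit an exponential decay curve through three NEC anchors
#'
#' Fits NEC(t) = a + b * exp(-k * (t - t0)) with t0 the first anchor year,
#' so that the curve interpolates all three anchors exactly. With three
#' parameters and three anchors the fit reduces, after eliminating a and b,
#' to a single root-finding problem in the decay rate k, solved by bracketed
#' bisection ([stats::uniroot()]).
#'
#' @param anchors A tibble with columns `year` and `nec` (three rows, years
#'   strictly increasing, NEC strictly decreasing, first value positive), as
#'   returned by [nec_anchors()].
#' @return An object of class `decay_curve`: list with asymptote `a`,
#'   amplitude `b` (both kgCaCO3 m-2 y-1), rate `k` (y-1), reference year
#'   `t0`, and the anchors.
#' @examples
#' fit_decay_curve(nec_anchors("2.6"))
#' @export
fit_decay_curve <- function(anchors) {
  stopifnot(is.data.frame(anchors), all(c("year", "nec") %in% names(anchors)))
  if (nrow(anchors) != 3) {
    stop("unfittable anchors: exactly three (year, NEC) anchors are required",
      call. = FALSE)
  }
  yr <- anchors$year
  y <- anchors$nec
  if (any(diff(yr) <= 0)) {
    stop("unfittable anchors: years must be strictly increasing", call. = FALSE)
  }
  if (y[1] <= 0) {
    stop("unfittable anchors: reference-year NEC must be positive", call. = FALSE)
  }
  if (any(diff(y) >= 0)) {
    stop("unfittable anchors: NEC must be strictly decreasing", call. = FALSE)
  }
  d1 <- yr[2] - yr[1]
  d2 <- yr[3] - yr[1]
  # Decay requires the drop ratio to sit strictly between the k->Inf limit (1)
  # and the k->0 (linear) limit d2/d1.
  ratio <- (y[1] - y[3]) / (y[1] - y[2])
  f <- function(k) (1 - exp(-k * d2)) / (1 - exp(-k * d1)) - ratio
  lo <- 1e-10
  hi <- 1
  n_expand <- 0
  while (f(hi) > 0 && n_expand < 60) {
    hi <- hi * 2
    n_expand <- n_expand + 1
  }
  if (f(lo) < 0 || f(hi) > 0) {
    stop("no exponential fit: decay rate not bracketed for these anchors",
      call. = FALSE)
  }
  k <- uniroot(f, c(lo, hi), tol = 1e-15)$root
  b <- (y[1] - y[2]) / (1 - exp(-k * d1))
  a <- y[1] - b
  curve <- structure(
    list(a = a, b = b, k = k, t0 = yr[1], anchors = anchors,
      rcp = attr(anchors, "rcp")),
    class = "decay_curve"
  )
  miss <- max(abs(predict(curve, yr) - y))
  if (miss > 1e-6) {
    stop("no exponential fit: anchors not interpolated to 1e-6", call. = FALSE)
  }
  curve
}

#' Evaluate a fitted NEC decay curve
#'
#' @param object A `decay_curve`.
#' @param year Numeric vector of years.
#' @param ... Unused.
#' @return Areal NEC (kgCaCO3 m-2 y-1) at `year`; constant at the reference
#'   (2005) value before the reference year.
#' @export
predict.decay_curve <- function(object, year, ...) {
  t_eff <- pmax(year, object$t0)
  object$a + object$b * exp(-object$k * (t_eff - object$t0))
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf(
    "<decay_curve%s> NEC(t) = %.4f + %.4f * exp(-%.5f * (t - %d))\n",
    if (is.null(x$rcp)) "" else paste0(" ", x$rcp), x$a, x$b, x$k, x$t0
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.decay_curve <- function(x, ...) {
  tibble::tibble(
    term = c("asymptote", "amplitude", "rate"),
    estimate = c(x$a, x$b, x$k),
    unit = c("kgCaCO3 m-2 y-1", "kgCaCO3 m-2 y-1", "y-1")
  )
}

#' @exportS3Method generics::glance
glance.decay_curve <- function(x, ...) {
  yr <- x$anchors$year
  tibble::tibble(
    rcp = x$rcp %||% NA_character_, t0 = x$t0,
    max_anchor_misfit = max(abs(predict(x, yr) - x$anchors$nec)),
    rel_2100 = relative_anomaly(x, 2100)
  )
}

#' Relative anomaly in reef carbonate production
#'
#' The dimensionless decline in NEC relative to its reference-year (2005)
#' value: (NEC(t0) - NEC(t)) / NEC(t0). Zero at and before the reference
#' year; exceeds 1 once the reef transitions to net dissolution (NEC < 0).
#'
#' @param curve A `decay_curve` from [fit_decay_curve()].
#' @param year Numeric vector of years (>= 1850).
#' @return Dimensionless fraction, non-decreasing in `year`.
#' @examples
#' relative_anomaly(fit_decay_curve(nec_anchors("2.6")), 2100) # ~0.7393
#' @export
relative_anomaly <- function(curve, year) {
  stopifnot(inherits(curve, "decay_curve"), all(year >= 1850))
  nec0 <- curve$a + curve$b
  (nec0 - predict(curve, year)) / nec0
}

#' Convert a relative calcification anomaly to global alkalinity/DIC fluxes
#'
#' A decline in reef calcification leaves alkalinity and DIC in the surface
#' ocean that calcification would otherwise have removed, in a 2:1 molar
#' ratio. Scaling the relative anomaly by the assumed historical global
#' carbonate production G0 (TgC y-1) gives the global sources:
#' DIC flux = rel * G0 * 1e12 / 12.011 mol y-1, alkalinity flux = twice that,
#' both reported in Pmol y-1.
#'
#' @param rel Dimensionless relative anomaly (>= 0), vectorised.
#' @param g0 Historical global carbonate production, TgC y-1 (> 0).
#' @return A tibble with columns `alk_pmol_yr` and `dic_pmol_yr`.
#' @examples
#' anomaly_to_global_fluxes(0.739286, 30)
#' @export
anomaly_to_global_fluxes <- function(rel, g0) {
  stopifnot(is.numeric(rel), is.numeric(g0), length(g0) == 1, g0 > 0)
  if (any(rel < 0)) {
    stop("negative relative anomaly: dissolution must come through the decay curve",
      call. = FALSE)
  }
  mol_c <- g0 * 1e12 / M_C
  dic <- rel * mol_c / 1e15
  tibble::tibble(alk_pmol_yr = 2 * dic, dic_pmol_yr = dic)
}

#' Build one reef-flux scenario
#'
#' Composes the pipeline for one of the nine ensemble members: fit the decay
#' curve for the RCP, evaluate annual relative anomalies from 2005, and scale
#' by the historical production G0 into global alkalinity and DIC fluxes.
#' Fluxes are zero before 2005 (no decline is simulated prior to 2005) and
#' are held at their 2100 value thereafter, where they are maintained until
#' the end of the series.
#'
#' @param rcp `"2.6"`, `"4.5"` or `"8.5"`.
#' @param g0 Historical global carbonate production, TgC y-1 (30/150/300 in
#'   the standard ensemble; any positive value is allowed).
#' @param years Annual grid (default 1850:2300).
#' @param hold_after Year after which fluxes are held constant (default 2100;
#'   `Inf` follows the fitted curve to the end).
#' @return A `reef_fluxes` tibble with columns `year`, `nec_areal`
#'   (kgCaCO3 m-2 y-1), `rel_anomaly`, `caco3_pmol_yr` (Pmol CaCO3-carbon
#'   y-1), `alk_pmol_yr`, `dic_pmol_yr` (Pmol y-1); attributes `rcp`, `g0`.
#' @examples
#' fl <- build_scenario("2.6", 30)
#' fl[fl$year == 2100, ]
#' @export
build_scenario <- function(rcp, g0, years = 1850:2300, hold_after = 2100) {
  key <- .normalize_rcp(rcp)
  stopifnot(is.numeric(g0), length(g0) == 1, g0 > 0)
  curve <- fit_decay_curve(nec_anchors(key))
  rel <- relative_anomaly(curve, pmin(years, hold_after))
  rel[years < 2005] <- 0
  fl <- anomaly_to_global_fluxes(rel, g0)
  out <- tibble::tibble(
    year = as.numeric(years),
    nec_areal = predict(curve, years),
    rel_anomaly = rel,
    caco3_pmol_yr = fl$dic_pmol_yr,
    alk_pmol_yr = fl$alk_pmol_yr,
    dic_pmol_yr = fl$dic_pmol_yr
  )
  class(out) <- c("reef_fluxes", class(out))
  attr(out, "rcp") <- key
  attr(out, "g0") <- g0
  attr(out, "curve") <- curve
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.reef_fluxes <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("year", "alk_pmol_yr", "dic_pmol_yr")],
    -"year", names_to = "flux", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$value,
    colour = .data$flux)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(labels = c(alk_pmol_yr = "Alkalinity",
      dic_pmol_yr = "DIC")) +
    ggplot2::labs(
      x = "Year", y = expression(Flux ~ (Pmol ~ y^{-1})), colour = NULL,
      title = sprintf("Reef-derived global fluxes, %s, G0 = %g TgC/y",
        toupper(sub("rcp", "RCP", attr(object, "rcp"))), attr(object, "g0"))
    )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
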