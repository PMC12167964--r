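# Ensemble orchestration and diagnostics: enhancement of anthropogenic CO2
# uptake relative to same-RCP reference runs, cumulative budgets, reef-box
# shares, carbon-budget conversions, and alkalinity-trend emergence.

#' Enhancement of ocean carbon uptake due to reef calcification decline
#'
#' Differences a scenario run against its same-RCP reference (no reef
#' fluxes): annual enhancement, cumulative enhancement (trapezoidal annual
#' sum), percent of the reference's cumulative uptake since the start of the
#' run, and the reef-shelf box's share of the enhancement. The two runs must
#' share configuration, years and CO2 pathway.
#'
#' @param scenario_run,reference_run `box_run` objects from
#'   [integrate_box()], identical except for the reef flux series.
#' @param control_run Optional preindustrial control `box_run` used to
#'   drift-correct the reference uptake in the percent diagnostic.
#' @return A `reef_enhancement` object: tibble with `year`, `d_flux`
#'   (PgC y-1), `cumulative` (PgC), `pct_of_reference` (%), `reef_share`
#'   (fraction, NA where the global enhancement < 1e-6 PgC y-1); attributes
#'   `peak`, `peak_year`, `rcp`, `g0`.
#' @export
compute_enhancement <- function(scenario_run, reference_run,
                                control_run = NULL) {
  stopifnot(inherits(scenario_run, "box_run"),
    inherits(reference_run, "box_run"))
  a_s <- scenario_run$annual
  a_r <- reference_run$annual
  if (!identical(a_s$year, a_r$year) ||
      !identical(a_s$pco2_atm, a_r$pco2_atm)) {
    stop("scenario and reference runs have mismatched years or CO2 forcing",
      call. = FALSE)
  }
  if (!identical(scenario_run$config, reference_run$config)) {
    stop("scenario and reference runs have different box configurations",
      call. = FALSE)
  }
  d_flux <- a_s$flux_global - a_r$flux_global
  d_reef <- a_s$flux_reef - a_r$flux_reef
  cumulative <- .cumtrapz_annual(d_flux)
  ref_flux <- a_r$flux_global
  if (!is.null(control_run)) {
    stopifnot(inherits(control_run, "box_run"))
    ref_flux <- ref_flux - control_run$annual$flux_global
  }
  ref_cum <- .cumtrapz_annual(ref_flux)
  pct <- ifelse(ref_cum > 0, 100 * cumulative / ref_cum, NA_real_)
  share <- ifelse(abs(d_flux) > 1e-6, d_reef / d_flux, NA_real_)
  # Peak over the perturbation period, ties broken by earliest year.
  per <- a_s$year >= 2005
  peak_i <- which(per)[which.max(d_flux[per])]
  out <- tibble::tibble(
    year = a_s$year, d_flux = d_flux, cumulative = cumulative,
    pct_of_reference = pct, reef_share = share
  )
  class(out) <- c("reef_enhancement", class(out))
  attr(out, "peak") <- d_flux[peak_i]
  attr(out, "peak_year") <- a_s$year[peak_i]
  attr(out, "rcp") <- scenario_run$rcp
  attr(out, "g0") <- scenario_run$g0
  out
}

.cumtrapz_annual <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  c(0, cumsum((x[-1] + x[-n]) / 2))
}

#' @exportS3Method generics::glance
glance.reef_enhancement <- function(x, ...) {
  at <- function(yr, col) if (yr %in% x$year) x[[col]][x$year == yr] else NA_real_
  tibble::tibble(
    rcp = attr(x, "rcp") %||% NA_character_,
    g0 = attr(x, "g0") %||% NA_real_,
    peak_pgc_yr = attr(x, "peak"), peak_year = attr(x, "peak_year"),
    cum_2100_pgc = at(2100, "cumulative"),
    cum_2300_pgc = at(2300, "cumulative"),
    pct_2300 = at(2300, "pct_of_reference"),
    reef_share_2006 = at(2006, "reef_share"),
    reef_share_2040 = at(2040, "reef_share"),
    reef_share_2300 = at(2300, "reef_share")
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.reef_enhancement <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$d_flux)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year",
      y = expression(Uptake ~ enhancement ~ (PgC ~ y^{-1})),
      title = sprintf("C uptake enhancement, %s, G0 = %g TgC/y",
        attr(object, "rcp") %||% "", attr(object, "g0") %||% NA))
}

#' Run the nine-member reef-feedback ensemble
#'
#' Performs the full experiment: one preindustrial control, one reference
#' run per RCP (atmospheric forcing only), and one scenario run per
#' (RCP, G0) pair with reef alkalinity/DIC fluxes, then computes enhancement
#' diagnostics for every member.
#'
#' @param config A [box_config()].
#' @param rcps RCP labels. Default all three.
#' @param g0s Historical production rates, TgC y-1. Default 30/150/300.
#' @param years Simulation years. Default 1850:2300.
#' @return A `reef_ensemble` object with `$summary` (one row per member:
#'   peak, peak year, cumulative 2100/2300, percent enhancement, reef shares),
#'   `$enhancements` (named list of `reef_enhancement`), `$references`,
#'   `$control` and `$runs`.
#' @export
run_ensemble <- function(config = box_config(),
                         rcps = c("2.6", "4.5", "8.5"),
                         g0s = c(30, 150, 300),
                         years = 1850:2300) {
  keys <- vapply(rcps, .normalize_rcp, character(1))
  pathways <- lapply(keys, rcp_co2_pathway)
  names(pathways) <- keys
  init <- init_preindustrial(config, pathways[[1]]$co2_ppm[1])
  control <- integrate_box(config, pathways[[1]], years = years, init = init,
    control = TRUE)
  references <- lapply(keys, function(k) {
    integrate_box(config, pathways[[k]], years = years, init = init, rcp = k)
  })
  names(references) <- keys
  runs <- list()
  enh <- list()
  for (k in keys) {
    for (g0 in g0s) {
      nm <- sprintf("%s_%g", k, g0)
      fl <- build_scenario(k, g0, years = years)
      runs[[nm]] <- integrate_box(config, pathways[[k]], fluxes = fl,
        years = years, init = init, rcp = k)
      enh[[nm]] <- compute_enhancement(runs[[nm]], references[[k]],
        control_run = control)
    }
  }
  summary <- purrr::map_dfr(enh, glance)
  structure(list(
    summary = summary, enhancements = enh, references = references,
    control = control, runs = runs, config = config
  ), class = "reef_ensemble")
}

#' @export
print.reef_ensemble <- function(x, ...) {
  cat(sprintf("<reef_ensemble> %d members\n", nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.reef_ensemble <- function(x, ...) {
  purrr::map_dfr(x$enhancements, tibble::as_tibble, .id = "member")
}

#' @exportS3Method generics::glance
glance.reef_ensemble <- function(x, ...) x$summary

#' @exportS3Method ggplot2::autoplot
autoplot.reef_ensemble <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$d_flux,
    colour = .data$member)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year",
      y = expression(Uptake ~ enhancement ~ (PgC ~ y^{-1})),
      colour = "Member",
      title = "Reef-feedback ensemble: uptake enhancement")
}

#' Time of emergence of an alkalinity trend from natural variability
#'
#' Monte-Carlo estimate of how long an annual reef-water alkalinity record
#' must be before a forced linear trend becomes statistically detectable
#' against AR(1) natural variability. For each realization, ordinary
#' least-squares trends are fitted over growing windows from the record
#' start; the trend variance is inflated by the AR(1) factor (1+phi)/(1-phi)
#' (reduced effective sample size), and emergence is the first window length
#' at which |trend| exceeds twice its adjusted standard error.
#'
#' @param trend Forced trend, mmol m-3 per century.
#' @param sigma Stationary standard deviation of natural variability,
#'   mmol m-3 (> 0).
#' @param phi Lag-1 autocorrelation of the AR(1) noise (|phi| < 1).
#' @param n_years Record length simulated per realization. Default 300.
#' @param n_realizations Monte-Carlo sample size. Default 500.
#' @param min_window Shortest window tested, years. Default 10.
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A `reef_emergence` object: tibble with one row per realization
#'   (`realization`, `emerged`, `years_to_detection`); attributes `median`,
#'   `q25`, `q75` (NA if the trend is zero or nothing emerges).
#' @export
time_of_emergence <- function(trend, sigma, phi, n_years = 300,
                              n_realizations = 500, min_window = 10,
                              seed = 1) {
  stopifnot(sigma > 0, abs(phi) < 1, n_years > min_window, min_window >= 5)
  if (trend == 0) {
    out <- tibble::tibble(realization = seq_len(n_realizations),
      emerged = FALSE, years_to_detection = NA_real_)
    class(out) <- c("reef_emergence", class(out))
    attr(out, "median") <- NA_real_
    attr(out, "q25") <- NA_real_
    attr(out, "q75") <- NA_real_
    attr(out, "no_emergence") <- TRUE
    return(out)
  }
  trend_yr <- trend / 100
  inflate <- (1 + phi) / (1 - phi)
  t_idx <- seq_len(n_years)
  # Cumulative-sum OLS over all window lengths at once.
  sx <- cumsum(t_idx)
  sxx <- cumsum(t_idx^2)
  w <- t_idx
  detect <- vapply(seq_len(n_realizations), function(i) {
    noise <- alkalinity_noise(sigma, phi, n_years, seed = seed + i)$anomaly
    y <- trend_yr * t_idx + noise
    sy <- cumsum(y)
    sxy <- cumsum(t_idx * y)
    syy <- cumsum(y^2)
    sxx_c <- sxx - sx^2 / w
    beta <- (sxy - sx * sy / w) / sxx_c
    sse <- pmax(syy - sy^2 / w - beta^2 * sxx_c, 0)
    var_beta <- sse / pmax(w - 2, 1) / sxx_c * inflate
    sig <- abs(beta) > 2 * sqrt(var_beta) & w >= min_window
    if (any(sig)) w[which(sig)[1]] else NA_real_
  }, numeric(1))
  out <- tibble::tibble(
    realization = seq_len(n_realizations),
    emerged = !is.na(detect),
    years_to_detection = detect
  )
  class(out) <- c("reef_emergence", class(out))
  qs <- quantile(detect, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  if (all(is.na(detect))) qs <- rep(NA_real_, 3)
  attr(out, "q25") <- qs[1]
  attr(out, "median") <- qs[2]
  attr(out, "q75") <- qs[3]
  attr(out, "no_emergence") <- all(is.na(detect))
  out
}

#' @exportS3Method generics::glance
glance.reef_emergence <- function(x, ...) {
  tibble::tibble(
    n = nrow(x), frac_emerged = mean(x$emerged),
    median_years = attr(x, "median"),
    q25_years = attr(x, "q25"), q75_years = attr(x, "q75")
  )
}
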