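# Synthetic forcing and variability generators: RCP atmospheric CO2
# pathways (packaged decadal fixture, annually interpolated), reef-location
# masks for gridded flux export, and AR(1) alkalinity variability.

#' Annual atmospheric CO2 pathway for an RCP
#'
#' Reads the packaged decadal concentration table (a synthetic approximation
#' to the published RCP concentration pathways; see the fixture header in
#' `inst/extdata/rcp_co2_synthetic.csv`) and interpolates linearly to annual
#' resolution, 1850-2300.
#'
#' @param rcp `"2.6"`, `"4.5"` or `"8.5"`.
#' @return A tibble with columns `year`, `co2_ppm`, `rcp`, `provenance`.
#' @examples
#' head(rcp_co2_pathway("8.5"))
#' @export
rcp_co2_pathway <- function(rcp) {
  key <- .normalize_rcp(rcp)
  path <- system.file("extdata", "rcp_co2_synthetic.csv", package = "reefcarb")
  tab <- utils::read.csv(path, comment.char = "#")
  years <- 1850:2300
  co2 <- approx(tab$year, tab[[key]], xout = years)$y
  tibble::tibble(year = as.numeric(years), co2_ppm = co2, rcp = key,
    provenance = "packaged-table")
}

#' Generate a synthetic reef-location mask on a regular grid
#'
#' Places `n_cells` reef cells at random within the tropical band of a
#' regular lat-lon grid (cell centres, degrees east/north, 0-based indices).
#' A stylised stand-in for a warm-water reef atlas; reef cells are drawn
#' uniformly among tropical cells, deterministic under `seed`. Cell areas
#' follow the spherical formula R^2 * dlon * (sin(lat2) - sin(lat1)).
#'
#' @param resolution Grid spacing, degrees. Default 2.
#' @param n_cells Number of reef cells (>= 1).
#' @param seed Integer seed.
#' @param lat_max Maximum absolute latitude of reef cells, degrees
#'   (<= 35). Default 30.
#' @return A `reef_mask` tibble: `lon_index`, `lat_index` (0-based), `lon`,
#'   `lat` (cell centres), `area_m2`, `reef` (logical), one row per grid
#'   cell.
#' @export
make_reef_mask <- function(resolution = 2, n_cells = 50, seed = 1,
                           lat_max = 30) {
  stopifnot(resolution > 0, n_cells >= 1, lat_max <= 35, lat_max > 0)
  r_earth <- 6371e3
  lon <- seq(-180 + resolution / 2, 180 - resolution / 2, by = resolution)
  lat <- seq(-90 + resolution / 2, 90 - resolution / 2, by = resolution)
  grid <- tidyr::expand_grid(lat = lat, lon = lon)
  dlam <- resolution * pi / 180
  grid$area_m2 <- r_earth^2 * dlam *
    (sin((grid$lat + resolution / 2) * pi / 180) -
     sin((grid$lat - resolution / 2) * pi / 180))
  grid$lon_index <- match(grid$lon, lon) - 1L
  grid$lat_index <- match(grid$lat, lat) - 1L
  tropical <- which(abs(grid$lat) <= lat_max)
  if (n_cells > length(tropical)) {
    stop("n_cells exceeds the number of tropical grid cells", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reef_idx <- sample(tropical, n_cells)
  grid$reef <- FALSE
  grid$reef[reef_idx] <- TRUE
  out <- grid[, c("lon_index", "lat_index", "lon", "lat", "area_m2", "reef")]
  out <- tibble::as_tibble(out)
  class(out) <- c("reef_mask", class(out))
  attr(out, "resolution") <- resolution
  attr(out, "seed") <- seed
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Distribute a global reef flux onto the reef cells of a mask
#'
#' Spreads the global alkalinity and DIC sources of one scenario year evenly
#' over all reef cells (equal flux density per unit reef area), zero
#' elsewhere. The area-weighted global sum reproduces the input global flux
#' to machine precision.
#'
#' @param fluxes A `reef_fluxes` tibble from [build_scenario()].
#' @param mask A `reef_mask` from [make_reef_mask()] with at least one reef
#'   cell.
#' @param year Year to export (must be present in `fluxes`).
#' @return The mask tibble with added columns `alk_flux` and `dic_flux`
#'   (mol m-2 y-1).
#' @export
grid_fluxes <- function(fluxes, mask, year) {
  stopifnot(is.data.frame(fluxes), is.data.frame(mask))
  if (!any(mask$reef)) stop("empty reef mask", call. = FALSE)
  i <- match(year, fluxes$year)
  if (is.na(i)) stop("year not present in the flux series", call. = FALSE)
  reef_area <- sum(mask$area_m2[mask$reef])
  out <- mask
  out$alk_flux <- ifelse(mask$reef,
    fluxes$alk_pmol_yr[i] * 1e15 / reef_area, 0)
  out$dic_flux <- ifelse(mask$reef,
    fluxes$dic_pmol_yr[i] * 1e15 / reef_area, 0)
  out
}

#' AR(1) natural variability of reef-water alkalinity
#'
#' Generates an annual anomaly series x_t = phi * x_{t-1} + eps_t with
#' innovation variance sigma^2 * (1 - phi^2), so the stationary standard
#' deviation equals `sigma`. Generated with [stats::arima.sim()]
#' (white noise for phi = 0); reproducible under `seed`.
#'
#' @param sigma Stationary standard deviation, mmol m-3 (> 0).
#' @param phi Lag-1 autocorrelation (|phi| < 1).
#' @param n_years Series length.
#' @param seed Integer seed.
#' @return A tibble with columns `year` (1..n) and `anomaly` (mmol m-3).
#' @export
alkalinity_noise <- function(sigma, phi, n_years, seed = 1) {
  stopifnot(sigma > 0, abs(phi) < 1, n_years >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sd_innov <- sigma * sqrt(1 - phi^2)
  x <- if (phi == 0) {
    rnorm(n_years, sd = sigma)
  } else {
    as.numeric(arima.sim(list(ar = phi), n = n_years, sd = sd_innov))
  }
  tibble::tibble(year = seq_len(n_years), anomaly = x)
}
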