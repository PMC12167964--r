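# Independent oracles used across the test suite. These deliberately avoid
# the package's solver code paths: speciation is re-derived from the
# equilibrium expressions and roots are located by brute-force grid scans.

# Total-alkalinity residual at a given pH, DIC/Alk in umol/kg. Same
# constants dialect as the package (the constants are the chemistry
# definition; the root-finding is what is being cross-checked).
oracle_alk_residual <- function(ph, dic_umol, alk_umol, temperature, salinity) {
  K <- carb_constants(temperature, salinity)
  h <- 10^(-ph)
  dic <- dic_umol * 1e-6
  alk <- alk_umol * 1e-6
  denom <- h^2 + K$K1 * h + K$K1 * K$K2
  hco3 <- dic * K$K1 * h / denom
  co3 <- dic * K$K1 * K$K2 / denom
  hco3 + 2 * co3 + K$TB * K$KB / (K$KB + h) + K$KW / h - h - alk
}

# Brute-force pCO2: two-stage pH grid scan, final resolution 1e-5 pH units.
oracle_pco2_gridscan <- function(dic_umol, alk_umol, temperature, salinity) {
  coarse <- seq(2, 12, by = 0.01)
  r <- oracle_alk_residual(coarse, dic_umol, alk_umol, temperature, salinity)
  ph0 <- coarse[which.min(abs(r))]
  fine <- seq(ph0 - 0.02, ph0 + 0.02, by = 1e-5)
  r <- oracle_alk_residual(fine, dic_umol, alk_umol, temperature, salinity)
  ph <- fine[which.min(abs(r))]
  K <- carb_constants(temperature, salinity)
  h <- 10^(-ph)
  co2 <- (dic_umol * 1e-6) * h^2 / (h^2 + K$K1 * h + K$K1 * K$K2)
  co2 / K$K0 * 1e6
}

# Brute-force decay fit: dense grid over (asymptote a, rate k) with the
# amplitude pinned by the first anchor, minimising squared misfit at the
# remaining anchors.
oracle_decay_gridscan <- function(anchors, a_grid, k_grid) {
  y0 <- anchors$nec[1]
  d <- anchors$year[-1] - anchors$year[1]
  y <- anchors$nec[-1]
  best <- c(a = NA_real_, k = NA_real_, sse = Inf)
  for (k in k_grid) {
    e1 <- exp(-k * d[1])
    e2 <- exp(-k * d[2])
    pred1 <- a_grid + (y0 - a_grid) * e1
    pred2 <- a_grid + (y0 - a_grid) * e2
    sse <- (pred1 - y[1])^2 + (pred2 - y[2])^2
    i <- which.min(sse)
    if (sse[i] < best[["sse"]]) best <- c(a = a_grid[i], k = k, sse = sse[i])
  }
  best
}

# Random but realistic surface-seawater states for solver batteries.
random_carb_states <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    dic = runif(n, 1850, 2350),
    alk_ratio = runif(n, 1.03, 1.20),
    temperature = runif(n, 0, 32),
    salinity = runif(n, 30, 40)
  ) |>
    dplyr::mutate(alk = dic * alk_ratio)
}
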