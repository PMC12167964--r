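# reefcarb

Coral reefs calcify, and net ecosystem calcification (NEC) removes total
alkalinity (Alk) and dissolved inorganic carbon (DIC) from seawater in a
2:1 molar ratio, raising seawater pCO2. As ocean warming and
acidification push global reef NEC down — and, under moderate-to-high
emissions, into net dissolution — the ocean retains Alk and DIC it would
otherwise have lost, surface pCO2 falls, and uptake of atmospheric CO2
increases. `reefcarb` quantifies this negative climate feedback at desk
scale, for marine biogeochemists and carbon-cycle modellers who want a
transparent, fully tested reimplementation of the pipeline without a
3-D ocean model.

The package provides:

- **Scenarios** — exponential decay curves
  NEC(t) = a + b·e^(−k(t−2005)) fitted through published areal NEC
  anchors per RCP, converted via relative anomalies and an assumed
  historical production G0 ∈ {30, 150, 300} TgC y⁻¹ into global
  Alk/DIC sources (Alk = 2 × DIC, Pmol y⁻¹).
- **Carbonate chemistry** — a total-scale seawater CO2-system solver
  (pH, pCO2, speciation, Revelle factor) with documented constants
  (Lueker 2000, Dickson 1990, Millero 1995, Weiss 1974).
- **Box ocean** — a four-box transient carbon cycle (reef shelf,
  tropical, high-latitude, deep) with prescribed atmospheric CO2,
  constant piston velocity, volume-conserving transport and reef-box
  flux injection.
- **Experiments** — the 9-member (RCP × G0) ensemble with reference and
  control runs, uptake-enhancement diagnostics, carbon-budget
  conversions (PgC → GtCO2), and time-of-emergence estimates for
  alkalinity trends in AR(1) reef noise.
- **Synthetic forcings** — RCP CO2 pathways (packaged synthetic table),
  reef-location masks, and seeded AR(1) alkalinity variability.

Everything is tibble-in / tibble-out with `tidy()`, `glance()` and
`autoplot()` methods on the fitted and simulated objects.

## Worked example

```r
library(reefcarb)

fl <- build_scenario("2.6", 30)   # minimal-decline member, RCP2.6, 30 TgC/y
fl[fl$year %in% c(2050, 2100, 2300), ]
#>   year nec_areal rel_anomaly caco3_pmol_yr alk_pmol_yr dic_pmol_yr
#> 1 2050     0.950      0.6607      0.001650    0.003301    0.001650
#> 2 2100     0.730      0.7393      0.001847    0.003693    0.001847
#> 3 2300     0.708      0.7393      0.001847    0.003693    0.001847
```

By 2100 the RCP2.6 NEC decline (relative anomaly 0.74 of the 2005 rate)
yields global alkalinity and DIC sources of 0.0037 and 0.0018
Pmol y⁻¹ — the printed 0.004 / 0.002 — held constant thereafter.
Running the full ensemble,

```r
ens <- run_ensemble()
ens$summary[, c("rcp", "g0", "peak_pgc_yr", "cum_2300_pgc")]
```

gives peak uptake enhancements from 0.015 PgC y⁻¹ (RCP2.6, 30) to
0.42 PgC y⁻¹ (RCP8.5, 300) and cumulative enhancements to 2300 of
4–112 PgC, with carbon and alkalinity bookkeeping closing to better
than 10⁻⁹ on every run. Detectability of the induced alkalinity
trend against reef natural variability:

```r
toe <- time_of_emergence(trend = 15, sigma = 30, phi = 0.6,
                         n_years = 400, n_realizations = 500, seed = 2)
glance(toe)
#>       n frac_emerged median_years q25_years q75_years
#> 1   500            1           88        24       172
```

a median of ~90 years before a 15 mmol m⁻³ century⁻¹ trend
emerges from σ = 30 mmol m⁻³ red noise — multidecadal to
multicentennial records are needed.

See `vignettes/reef-carbonate-feedback.Rmd` for the model descriptions,
parameter choices and limitations.

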