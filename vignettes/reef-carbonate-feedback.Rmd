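---
title: "The coral reef carbonate feedback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coral reef carbonate feedback: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefcarb)
```

## The problem

Coral reef communities calcify. Net ecosystem calcification (NEC — gross
calcification minus CaCO3 dissolution) removes total alkalinity (Alk) and
dissolved inorganic carbon (DIC) from reef waters in a 2:1 molar ratio,
which *raises* seawater pCO2. As warming and acidification drive global
reef NEC down — and eventually negative, into net dissolution — that
removal weakens or reverses: relative to the unperturbed state, the ocean
gains Alk and DIC in a 2:1 ratio, surface pCO2 falls, and the ocean takes
up more CO2 from the atmosphere. This is a negative climate feedback,
absent from current Earth system models. `reefcarb` quantifies it at desk
scale: scenario construction, carbonate chemistry, a reduced-complexity
transient ocean, and detectability diagnostics.

## Scenario construction

Global-mean areal reef NEC is anchored at three published central
estimates per RCP: 2.8 kgCaCO3 m⁻² y⁻¹ in 2005, declining to
0.95 / −0.63 / −1.45 in 2050 and 0.73 / −1.39 / −1.57 in
2100 under RCP2.6 / RCP4.5 / RCP8.5. Through each triple we fit

$$\mathrm{NEC}(t) = a + b\,e^{-k\,(t - 2005)},$$

a three-parameter exponential decay that interpolates the three anchors
exactly. Eliminating $a$ and $b$ reduces the fit to one equation in $k$,
solved by bracketed bisection; anchors that do not decrease strictly are
refused ("unfittable anchors"). The fit is checked in the test suite
against a brute-force grid scan over $(a, k)$.

The dimensionless **relative anomaly** $r(t) = (\mathrm{NEC}(2005) -
\mathrm{NEC}(t)) / \mathrm{NEC}(2005)$ is zero before 2005 (no decline is
simulated prior to 2005) and exceeds 1 once NEC turns negative. Because
only ratios of the areal anchors enter, no global reef-area value is
needed: the anomaly is scaled directly by an assumed historical global
carbonate production $G_0 \in \{30, 150, 300\}$ TgC y⁻¹
(0.25 / 1.25 / 2.50 PgCaCO3 y⁻¹), spanning the observational
range. The global sources are then

$$F_\mathrm{DIC}(t) = r(t)\, G_0 \times 10^{12} / 12.011 \ \mathrm{mol\,y^{-1}},
\qquad F_\mathrm{Alk} = 2\,F_\mathrm{DIC},$$

reported in Pmol y⁻¹. Molar masses are 12.011 (C) and 100.0869
(CaCO3); printed figures are reproduced by rounding outputs only, never
intermediates.

**Post-2100 behaviour.** Fluxes are held at their 2100 values through
2300. We examined the alternative of following the fitted curve to 2300:
the curve drifts a further 1.1% (RCP2.6) and 3.9% (RCP4.5) beyond 2100
relative to the 2100 value, whereas the scenarios are defined as
maintaining their 2100 fluxes on multicentennial timescales. The hold
keeps the series non-decreasing and effectively flat after 2150 either
way (curve change 2150→2300 is < 1%). The decline-saturation
diagnostic $r(2050)/r(2300) > 0.75$ ("most of the decline occurs before
2050") is evaluated on the fitted curve itself.

## Carbonate chemistry

The solver works on the total pH scale with one versioned constants
dialect: K1/K2 from Lueker et al. (2000), KB from Dickson (1990), KW from
Millero (1995), K0 from Weiss (1974), total boron from salinity
(Uppström 1974). Alkalinity is carbonate + borate + water; nutrients are
excluded because the box model carries no nutrient state, and the
fugacity correction is neglected. Internal units are mol kg⁻¹ with a
fixed reference density of 1025 kg m⁻³ at the mol m⁻³
interface.

Given DIC and Alk, the alkalinity residual is strictly decreasing in
[H⁺], so pH is found by a safeguarded Newton iteration bracketed on
pH ∈ [2, 12] (bisection fallback whenever a Newton step leaves the
bracket), converged to a residual below 10⁻¹³ mol kg⁻¹.
The inverse problem (`dic_from_pco2`) fixes [CO2*] = K0 pCO2 and solves
the same balance by bisection. Both are cross-checked in the tests against
an independent brute-force pH grid scan at 10⁻⁵ pH resolution over
a 1000-state random battery. The Revelle factor and
∂pCO2/∂Alk, ∂pCO2/∂DIC use central finite differences with
a relative step of 10⁻⁴ (halving the step changes the Revelle
factor by < 0.1%). At every realistic surface state
|2 ∂pCO2/∂Alk| > |∂pCO2/∂DIC|: the 2:1 addition always
lowers pCO2, the sign of the feedback.

## The four-box ocean

The transient ocean is deliberately minimal: a reef-shelf surface box
(1% of the ocean surface, 100 m deep — an explicit "reef regions" analog),
an open tropical surface box (75%), a high-latitude surface box (24%),
and a deep reservoir making up the rest of 1.335 × 10¹⁸ m³.
Overturning (22 Sv) sinks at high latitude and upwells into the tropical
box; bidirectional mixing connects reef–tropical (10 Sv),
tropical–deep (30 Sv) and high-latitude–deep (60 Sv). The flow
matrix is volume-conserving by construction, so volume-weighted tracer
totals are conserved to machine precision. Gas exchange uses a constant
piston velocity of 4 m d⁻¹ (≈ 17 cm h⁻¹, the global-mean
order) — no wind fields at desk scale:

$$F = k_w\,K_0\,(p\mathrm{CO_2^{atm}} - p\mathrm{CO_2^{box}})\,A.$$

Box temperatures are fixed (reef 27, tropical 24, high-latitude 4, deep
3 °C, S = 35) except for an optional — default on — linear SST ramp
from 2005 of 1.0 / 1.8 / 3.5 °C century⁻¹ under
RCP2.6 / 4.5 / 8.5, stabilising in 2100 / 2150 / 2250; solubility and
chemistry respond to the ramp. Time stepping is explicit Euler at
dt = 0.05 y; cumulative uptake changes by < 0.5% against dt = 0.005 y.

**Preindustrial state.** Alkalinity is uniform at 2.40 mol m⁻³
(there is no riverine/burial alkalinity cycle, so uniform Alk is exactly
stationary under transport). The four-box DIC distribution is solved
directly for stationarity (transport + gas exchange = 0 in every box)
with a quasi-Newton root finder. Individual boxes then carry non-zero
air–sea fluxes balanced by circulation — as the real preindustrial
ocean does; a per-box zero-flux equilibrium is impossible with
heterogeneous temperatures and connected volume-conserving transport,
since it would force uniform DIC *and* per-box gas equilibrium at
different temperatures. The *global* preindustrial flux is zero to
∼10⁻¹³ PgC y⁻¹, and a 500-year control drifts by less
than 10⁻³ PgC y⁻¹.

**Calibration.** A reduced model of this kind has no independent
calibration targets; transports and piston velocity were set once to
standard magnitudes and checked only against preindustrial stationarity
and a plausible historical uptake — the configuration gives
≈1.9 PgC y⁻¹ in the mid-1990s and 2.3 PgC y⁻¹ in 2005,
consistent with the ∼2 PgC y⁻¹ observational estimate for the
1990s–2000s.

## Experiments and diagnostics

The standard ensemble is one preindustrial control, three reference runs
(atmospheric CO2 only) and nine scenario runs (RCP × $G_0$),
1850–2300, with reef fluxes injected wholly into the reef-shelf box
from 2005. Enhancement is scenario minus *same-RCP reference* — the
control is used only to drift-correct the reference uptake in the
percent diagnostic. Cumulative sums are trapezoidal over annual means;
the peak is located over 2005–2300 with ties broken by the earliest
year; the reef-box share of enhancement is reported where the global
enhancement exceeds 10⁻⁶ PgC y⁻¹.

With the default configuration the ensemble reproduces the structure of
the large-model result: enhancement is non-negative everywhere,
smallest-peak member RCP2.6₃₀ and largest RCP8.5₃₀₀,
near-linear in $G_0$, and similar (within ≈22%) between RCP4.5 and
RCP8.5 at fixed $G_0$ because calcification decline saturates under
moderate forcing. The two-region analog reproduces the qualitative
export of unequilibrated water: the reef-box share of enhancement falls
from ≈0.8 at onset to ≈0.45 by 2040. The quantitative reef-share
trajectories of the 3-D model depend on resolved circulation and are
intentionally not targeted.

Bookkeeping invariants hold on every run: cumulative air–sea flux plus
cumulative reef DIC input equals the DIC inventory change, and the Alk
inventory change equals the reef Alk input, both to better than
10⁻⁹ relative; a zero-amplitude flux series reproduces its
reference run bitwise (identical code path).

`pgc_to_gtco2()` converts cumulative enhancements to the GtCO2 scale of
carbon-budget statements (1 PgC = 3.664 GtCO2).

## Synthetic forcings and detectability

*CO2 pathways.* Annual 1850–2300 concentrations per RCP are linearly
interpolated from a packaged decadal table — a synthetic approximation to
the published RCP concentration pathways (see the fixture header), not
the official data. Invariants: ≈284.7 ppm in 1850, RCP8.5 ≥ RCP4.5
≥ RCP2.6 after 2050, RCP2.6 peaks and declines before 2100.

*Reef masks.* `make_reef_mask()` scatters reef cells uniformly within
|lat| ≤ 30° on a regular grid (spherical cell areas) — a stylised
stand-in for a reef atlas, sufficient for testing conservative gridded
export: `grid_fluxes()` spreads the global flux evenly per unit reef
area and reproduces the global total to machine precision.

*Alkalinity variability.* Reef-water alkalinity is extremely noisy;
`alkalinity_noise()` generates AR(1) anomalies with stationary standard
deviation σ and lag-1 autocorrelation φ. `time_of_emergence()`
fits OLS trends over growing windows and inflates the trend variance by
(1+φ)/(1−φ) — the effective-sample-size correction, using the
generating φ since the detection rule is a design choice here, not an
estimate — declaring emergence when |trend| > 2 SE. Windows shorter than
10 years are not tested (trend estimates on a handful of annual points
are meaningless); the Monte-Carlo median and quartiles are reproducible
under a fixed seed. Simulated mean trends of 10–50 mmol m⁻³
century⁻¹ against σ of tens of mmol m⁻³ give
multidecadal-to-multicentennial emergence times.

## What the synthetic setup does and does not show

The generators emulate the *structure* of the study conditions — scenario
ordering, preindustrial baselines, 2:1 stoichiometry, red-noise
variability — not real reef locations, observed alkalinity
climatologies, or resolved circulation. Passing tests therefore
demonstrate correctness of the scenario arithmetic, chemistry,
conservation and qualitative feedback behaviour, and order-of-magnitude
agreement of the uptake enhancement; they do not validate the spatial
pattern or the precise GCM values, which depend on 3-D transport this
package intentionally does not model.

Problem sizes used throughout (451-year runs at dt = 0.05, 13-run
ensemble, 1000-state chemistry batteries, 500-realization Monte-Carlo)
were chosen as the package's standard configuration; the full ensemble
runs in well under a minute on one CPU.

## Worked example

```{r example, eval = FALSE}
library(reefcarb)

fl <- build_scenario("2.6", 30)
fl[fl$year == 2100, c("alk_pmol_yr", "dic_pmol_yr")]
# alkalinity 0.00369, DIC 0.00185 Pmol/y -> printed 0.004 / 0.002

ens <- run_ensemble()
ens$summary
autoplot(ens)
```

## Known limitations

- No emissions-driven atmosphere: prescribed CO2 means the enhanced
  uptake does not feed back on atmospheric concentrations (this
  overstates the enhancement an interactive model would give).
- Reef NEP is held constant; spatial heterogeneity of the decline, other
  stressors and adaptive capacity are not represented.
- The four-box circulation is a caricature: reef-region residence times,
  and hence the reef-share trajectories, are qualitative only.
- One carbonate-constants dialect, surface pressure only, no
  nutrient alkalinity, no saturation-state dissolution kinetics.
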