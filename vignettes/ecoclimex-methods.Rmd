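---
title: "Methods: the ecoclimatic-index suitability model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ecoclimatic-index suitability model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclimex)
```

## The model

`ecoclimex` implements a CLIMEX-style mechanistic species distribution
model. Climatic suitability for a species at a location is summarised by
the **Ecoclimatic Index (EI)**, a 0–100 score that combines an annual
growth potential with annual accumulations of climatic stress:

$$
\mathrm{EI} \;=\; \mathrm{GI_A} \cdot
\Bigl(1-\tfrac{\mathrm{CS}}{100}\Bigr)
\Bigl(1-\tfrac{\mathrm{HS}}{100}\Bigr)
\Bigl(1-\tfrac{\mathrm{DS}}{100}\Bigr),
\qquad \mathrm{EI}=0 \text{ if } \mathrm{DD} < \mathrm{PPD}.
$$

The components, all computed on a 52-week year interpolated from monthly
climate normals, are:

* **Weekly growth index** $GI_w = TI_w \cdot MI_w$, the product of a
  temperature index and a soil-moisture index. Each is a trapezoidal
  response: zero at or outside a pair of limiting values, one on an
  optimal plateau, linear in between. The annual growth index is
  $GI_A = 100 \cdot \frac{1}{52}\sum_w GI_w$.
* **Cold, heat and dry stress** (CS, HS, DS): linear accumulations of
  weekly threshold exceedances, scaled by a weekly rate and capped at
  100%. Cold stress accumulates shortfalls of weekly minimum temperature
  below `TTCS` at rate `|THCS|`; heat stress accumulates excesses of
  weekly maximum temperature above `TTHS` at rate `THHS`; dry stress
  counts weeks with soil moisture below `SMDS` at rate `|HDS|`.
* **Degree-days** $DD = \sum_w 7\,\max(0,\; \bar T_w - DV0)$, the annual
  thermal sum above the developmental base temperature. Where
  $DD < PPD$ the species cannot complete a generation in a year and EI
  is forced to zero regardless of growth.

Maps are classified as *unsuitable* (EI = 0), *low* suitability
(0 < EI < 30) and *high* suitability (EI ≥ 30).

This is a re-implementation of the model *structure*, not a bit-exact
clone of the commercial CLIMEX software, whose internal accumulation
equations are not public. The weekly multiplicative growth composition and
the linear capped stress accumulation are the simplest forms that
reproduce the documented threshold, rate and directionality semantics;
all conclusions drawn from this package should be read with that in mind.

## Species parameters

The shipped default parameter set describes *Urochloa panicoides*
(liverseed grass), an invasive C4 pasture weed of tropical and
subtropical climates:

```{r}
species_params()
```

Temperature thresholds are in °C, moisture values are fractions of soil
holding capacity, stress rates are per week, and `PPD` is in °C·days.
Two published values deserve comment:

* The dry-stress threshold is stated in one place as 0.01 and tabulated
  as 0.1; the tabulated 0.1 is the default, and `species_params(SMDS =
  0.01)` (or `--param SMDS=0.01` on the command line) selects the
  alternative.
* `PPD = 1517` is described as an average of the reported 1202–1723
  °C·day range although the arithmetic mean of those extremes is 1462.5;
  the published 1517 is used.

The boundary value EI = 30 is assigned to the *high* class so that the
three classes partition [0, 100].

## Weekly interpolation and the soil-moisture bucket

Monthly normals (minimum and maximum temperature, precipitation, relative
humidity at 09:00 and 15:00) are interpolated to a 364-day, 52-week year:
each variable linearly between consecutive month midpoints, circularly
across December–January. Weekly values are rescaled per cell so annual
precipitation is conserved exactly; weekly humidity is the mean of the two
observation times. A 52 × 7 year keeps the week-rate parameter units exact
and makes conservation checks trivial.

Soil moisture follows a weekly bucket model:

$$
SM_w = \mathrm{clamp}\!\left(SM_{w-1} + \frac{P_w - E_w}{C},\; 0,\;
\text{ceiling}\right),
\qquad E_w = k \cdot \max(0, \bar T_w)\,(1.05 - rh_w),
$$

with capacity $C$ = 100 mm and $k$ = 1 mm week⁻¹ °C⁻¹ by default. The
annual cycle is spun up until it converges (maximum weekly change below
10⁻⁶); years in which no clamp engages advance the state linearly and are
fast-forwarded analytically, so convergence is reached in a handful of
iterations even for cells whose water balance is nearly neutral. If the
spin-up budget (default 100 years) is exhausted a warning is issued and
the last cycle returned.

The bucket **ceiling** defaults to 2.5, the conventional upper bound of
the CLIMEX soil-moisture scale. It is deliberately *not* the species' wet
limit `SM3`: the ceiling is the physical saturation of the bucket (water
beyond it runs off), whereas `SM3` acts through the moisture trapezoid. A
ceiling placed at `SM3` would pin every wet-equilibrium cell exactly onto
the trapezoid's upper zero and declare the wet tropics unsuitable for a
tropical grass — a structurally wrong configuration, though the argument
remains available for experimentation.

Two further exposure choices are deliberate and conservative: growth
responds to weekly *mean* temperature, cold stress to weekly *minimum*,
heat stress to weekly *maximum*. Temperature stresses weight weeks by the
exceedance magnitude (°C·weeks); dry stress counts weeks below threshold,
because soil-moisture deficits are bounded in [0, `SMDS`] and
magnitude-weighting would make the dry rate unit effectively different
from the published week⁻¹ one. Both weightings are switchable via
`stress_modes` in `run_grid()`. Wet stress is not implemented: the
parameter set defines none, and `SM3` enters only via the trapezoid.

## The synthetic climate generator

`generate_climate_grid()` produces seeded grids with the qualitative
structure the analysis assumes, so the full pipeline runs without any
external data: monthly mean temperature decreases with absolute latitude
(0.55 °C per degree from a 27 °C equator), a seasonal cycle grows with
latitude (0.35 °C amplitude per degree) with its warm phase in July north
of the equator and January south of it, precipitation follows three
bands (wet tropics 150, dry subtropics 20, moderate temperate
60 mm·month⁻¹), humidity is a fixed morning/afternoon pair around 0.70,
and Gaussian noise (sd 0.5 °C) is added to the monthly mean temperature
only — minima and maxima are derived afterwards, so `tmin ≤ tmax` holds by
construction. On the default 36 × 72 globe this yields the expected
pattern: high suitability in the wet tropics, dry-stressed unsuitable
subtropics, a temperate low-suitability fringe, and cold-gated poles.

What the generator does **not** emulate: continents and oceans (all cells
are land unless a mask is supplied), orography, realistic humidity
seasonality, interannual variability, or the marginal distributions of any
real climatology. Passing tests therefore demonstrate correctness of the
*method* — thresholds, accumulation, classification, protocol — on data
with the right structure, not agreement with the published global maps,
which additionally depend on licensed climate rasters and the closed
commercial implementation.

Occurrence sampling draws points over cells with probability proportional
to $EI^{\gamma}$ (default $\gamma = 1$), contaminates a small fraction
(default 2%) uniformly to emulate database noise, and jitters points
within cells by up to 5 km. The default 730 points matches the scale of a
typical unthinned download for a widespread invasive weed; greedy 10-km
thinning then reduces them in the same spirit as the published
730 → 355 filtering (the exact historical algorithm is not recoverable,
so counts are not comparable record-for-record).

## Sensitivity protocol and scenarios

`run_sensitivity()` applies the published one-at-a-time design: each of
the 15 parameters is set to its low and high value (±1 °C for temperature
thresholds, ±10% for moisture and rate parameters, ±20 °C·days for `PPD`)
with everything else at the adjusted values — 30 runs against one
baseline. Area shares per class use cosine-latitude weights (equal-angle
cells shrink poleward; plain cell counts are attached as an attribute),
and changes are reported in percentage points alongside a relative
percentage. The weekly climate and the soil-moisture spin-up are shared
across all runs, since no species parameter enters the water balance.

One behaviour of the default synthetic globe is worth knowing when
interpreting sensitivity output: with the default 10 °C diurnal range,
cells cold enough to accumulate meaningful cold stress are already below
the degree-day gate, so perturbing `TTCS`/`THCS` leaves class shares
unchanged. On frost-prone variants (e.g. `climate_spec(diurnal_range =
30)` — warm days, cold nights) cold stress becomes the binding constraint
at the cold margin and the perturbations reproduce the expected
directions: lowering the cold-stress threshold or rate shrinks the
unsuitable share, raising them cannot shrink it.

Climate-change scenarios are uniform transforms: a temperature shift
applied to `tmin`/`tmax` and a multiplicative precipitation factor, with
humidity unchanged (no published humidity delta exists for the summarised
projection). The defaults scale the full-century change (+2.11 °C, −14%
precipitation by 2100 relative to a 1975-centred baseline) linearly with
elapsed time — fractions 0.60, 0.84 and 1.00 for 2050, 2080 and 2100.
The per-year global-model fields behind the original projection are not
public, so this linear scaling is a transparent stand-in, fully
configurable via `scenario_transform()`. Scenario output includes
per-cell EI and cold-stress deltas; warming never increases accumulated
cold stress (a provable monotonicity of the accumulation), and reduced
precipitation never shrinks the dry-stressed area in a moisture-limited
band.

## Numerical choices and verification scale

* Trapezoids are exact at all four breakpoints and continuous throughout.
* The 364-day year makes weekly rates and degree-day sums exact
  multiples of 7.
* Greedy thinning sorts points by (lat, lon, species) before retention,
  making it deterministic; distances are haversine with a 6371-km mean
  Earth radius (sub-0.5% error, immaterial at a 10-km radius).
* Overlay assigns a point to the nearest cell centre within half the
  median cell spacing per axis; anything farther is counted "outside".
* All generators take integer seeds and restore the caller's RNG state.

The test suite verifies the vectorised engine against an independent
per-cell scalar reference (plain loops, naive spin-up) to 10⁻¹⁰ on a
500-cell synthetic grid, thinning against a brute-force oracle on 200
points, and the full command-line pipeline end-to-end on a 36 × 72 globe —
sizes chosen to exercise every regime (tropical optimum, dry band, cold
margin) while keeping a full run in seconds.

## Known limitations

* Not a CLIMEX clone: absolute EI values are comparable in structure, not
  numerically, to published CLIMEX outputs.
* No diapause, light, wet-stress or irrigation components, and no species
  interactions: none are parameterised for this species.
* The soil-moisture model is a single-bucket weekly balance with a crude
  evapotranspiration proxy; it is adequate for threshold-crossing
  semantics, not for hydrological realism.
* Synthetic grids are structurally, not statistically, realistic; results
  on them validate the machinery, never a real-world risk map.
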