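# ecoclimex

Mechanistic climate-suitability modelling around the **Ecoclimatic Index
(EI)**, in the CLIMEX tradition, parameterised for the invasive C4 grass
*Urochloa panicoides* (liverseed grass). The package is aimed at
invasion-risk and weed-science workflows: given monthly climate normals it
predicts where a species can grow and persist, quantifies how sensitive
that prediction is to each biological parameter, and projects the map
under climate-change transforms — all runnable offline on seeded synthetic
climate grids.

## The model

Per grid cell, on a 52-week year interpolated from monthly normals:

```
GI_w = TI(tmean_w) * MI(SM_w)            weekly growth (trapezoids)
GI_A = 100 * mean_w(GI_w)                annual growth index, 0-100

CS = min(100, 100*|THCS| * sum_w max(0, TTCS - tmin_w))   cold stress
HS = min(100, 100* THHS  * sum_w max(0, tmax_w - TTHS))   heat stress
DS = min(100, 100*|HDS|  * #{w: SM_w < SMDS})             dry stress
DD = sum_w 7 * max(0, tmean_w - DV0)                      degree-days

EI = GI_A * (1-CS/100)(1-HS/100)(1-DS/100),  forced to 0 if DD < PPD
```

`TI`/`MI` are trapezoidal responses over `(DV0, DV1, DV2, DV3)` and
`(SM0, SM1, SM2, SM3)`; `SM_w` comes from a weekly soil-moisture bucket.
Classes: unsuitable (EI = 0), low (0 < EI < 30), high (EI ≥ 30). The 15
shipped parameter defaults are the adjusted *U. panicoides* values
(`species_params()`); a one-at-a-time sensitivity protocol perturbs each
to published low/high bounds. This is an open re-implementation of the
model structure, not a bit-exact clone of the commercial CLIMEX software.

## Worked example

```r
library(ecoclimex)

grid <- generate_climate_grid(climate_spec(n_lat = 18, n_lon = 36, seed = 42))
map  <- run_grid(grid)                      # EI + class per cell
round(area_shares(map), 2)
#> unsuitable        low       high
#>      51.53      25.62      22.85
```

About half of this synthetic globe is unsuitable (cold-gated poles and
the dry subtropical band), a quarter marginal, and the wet tropics highly
suitable. Validating against (synthetic) occurrence records:

```r
occ     <- sample_occurrences(map, occurrence_spec(n_points = 300, seed = 42))
thinned <- thin_by_radius(occ, 10)          # greedy 10-km spatial thinning
nrow(occ); nrow(thinned)
#> [1] 300
#> [1] 140
overlay_occurrences(thinned, map)
#> Occurrence overlay: 140 points, 0 outside grid
#> unsuitable        low       high
#>       5.71      29.29      65.00
```

65% of thinned records fall in high-suitability cells versus a 22.85%
high-class area share — occurrences concentrate where the model says they
should. Sensitivity and scenarios:

```r
sens <- run_sensitivity(grid)               # 15 parameters x low/high
proj <- run_scenarios(grid)                 # 2050 / 2080 / 2100 transforms
```

A command-line pipeline wraps the same functions:

```sh
Rscript inst/cli/ecoclimex.R generate --seed 1 --nlat 36 --nlon 72 --out data
Rscript inst/cli/ecoclimex.R run --climate data/climate.csv \
    --occurrences data/occurrences.csv --out results
Rscript inst/cli/ecoclimex.R sensitivity --climate data/climate.csv --out results
Rscript inst/cli/ecoclimex.R scenario --climate data/climate.csv --out results
```

See `vignettes/ecoclimex-methods.Rmd` for the full model description,
parameter table, and design rationale.

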