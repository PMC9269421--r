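# Ecoclimatic-index engine: weekly growth indices, soil-moisture bucket,
# stress accumulation, degree-days, EI and the 3-class suitability label.
#
# This is an open reimplementation of the CLIMEX model structure, not a
# bit-exact clone of the commercial software: the weekly composition
# GI_w = TI_w * MI_w, linear (capped) stress accumulation, and the bucket
# soil-moisture model are the documented structural choices.

EI_CLASSES <- c("unsuitable", "low", "high")

#' Trapezoidal temperature growth index
#'
#' Weekly temperature suitability: 0 at or below the limiting low
#' temperature `DV0` and at or beyond the limiting high temperature `DV3`,
#' 1 on the optimal plateau `[DV1, DV2]`, linear ramps in between.
#'
#' @param tmean weekly mean temperature(s), deg C; vector or matrix.
#' @param p `ecx_params`.
#' @return index values in `[0, 1]`, same shape as `tmean`.
#' @examples
#' p <- species_params()
#' temperature_index(c(4, 14.5, 25, 35, 40, 45), p)
#' @export
temperature_index <- function(tmean, p) {
  trapezoid(tmean, p$DV0, p$DV1, p$DV2, p$DV3)
}

#' Trapezoidal soil-moisture growth index
#'
#' Same shape rules as [temperature_index()] over the moisture breakpoints
#' `(SM0, SM1, SM2, SM3)`; the argument is soil moisture as a fraction of
#' bucket holding capacity.
#'
#' @param sm soil-moisture value(s); vector or matrix, `>= 0`.
#' @param p `ecx_params`.
#' @return index values in `[0, 1]`.
#' @export
moisture_index <- function(sm, p) {
  trapezoid(sm, p$SM0, p$SM1, p$SM2, p$SM3)
}

# Piecewise-linear trapezoid: 0 outside (a, d), 1 on [b, c], linear ramps.
# Exact at all four breakpoints; continuous everywhere.
trapezoid <- function(x, a, b, c, d) {
  up <- (x - a) / (b - a)
  down <- (d - x) / (d - c)
  out <- pmin(1, pmin(up, down))
  out[x <= a | x >= d] <- 0
  dim(out) <- dim(x)
  out
}

#' Soil-moisture bucket configuration
#'
#' The weekly water balance `SM_w = clamp(SM_{w-1} + (P_w - E_w)/capacity,
#' 0, ceiling)` with evapotranspiration `E_w = et_coefficient *
#' max(0, tmean_w) * (1.05 - rh_w)` (mm/week). The cycle is iterated over
#' repeated years until the annual trajectory converges (max weekly change
#' < 1e-6) or `spinup_years` is reached.
#'
#' @param capacity bucket holding capacity, mm (> 0).
#' @param et_coefficient evapotranspiration scaling, mm/week per deg C.
#' @param initial_sm starting soil moisture, fraction of capacity.
#' @param spinup_years maximum annual iterations (>= 1).
#' @param ceiling physical saturation bound of the bucket in soil-moisture
#'   units (default 2.5, the conventional upper bound of the moisture
#'   scale); water beyond it is runoff. The species' wet limit `SM3` acts
#'   through the moisture trapezoid, not through this clamp, so a ceiling
#'   at or above `SM3` would pin saturated cells onto the trapezoid's zero
#'   and is not the intended configuration.
#' @return `ecx_sm_config` object.
#' @export
soil_moisture_config <- function(capacity = 100, et_coefficient = 1,
                                 initial_sm = 0.5, spinup_years = 100,
                                 ceiling = 2.5) {
  check_number(capacity, "capacity")
  if (capacity <= 0) ecx_stop("capacity must be > 0")
  check_number(et_coefficient, "et_coefficient", lo = 0)
  check_number(initial_sm, "initial_sm", lo = 0)
  check_number(spinup_years, "spinup_years", lo = 1)
  check_number(ceiling, "ceiling", lo = 0)
  structure(list(capacity = capacity, et_coefficient = et_coefficient,
                 initial_sm = initial_sm,
                 spinup_years = as.integer(spinup_years), ceiling = ceiling),
            class = "ecx_sm_config")
}

#' Weekly soil-moisture series from the bucket model
#'
#' Accepts either 52-length vectors (one cell) or n x 52 matrices (all cells
#' at once); the recurrence is identical. Issues a warning and returns the
#' last cycle if the spin-up limit is reached without convergence.
#'
#' @param precip weekly precipitation, mm/week.
#' @param tmean weekly mean temperature, deg C.
#' @param rh weekly relative humidity, fraction.
#' @param cfg `ecx_sm_config`.
#' @return soil-moisture series with the shape of the inputs, in fractions
#'   of holding capacity.
#' @export
soil_moisture_series <- function(precip, tmean, rh,
                                 cfg = soil_moisture_config()) {
  stopifnot(inherits(cfg, "ecx_sm_config"))
  vec <- is.null(dim(precip))
  if (vec) {
    precip <- matrix(precip, nrow = 1)
    tmean <- matrix(tmean, nrow = 1)
    rh <- matrix(rh, nrow = 1)
  }
  if (ncol(precip) != 52L) ecx_stop("weekly series must have 52 weeks")
  et <- cfg$et_coefficient * pmax(0, tmean) * (1.05 - rh)
  flux <- (precip - et) / cfg$capacity
  n <- nrow(precip)
  sm <- matrix(0, n, 52)
  state <- rep(cfg$initial_sm, n)
  converged <- FALSE
  for (yr in seq_len(cfg$spinup_years)) {
    prev <- sm
    start <- state
    clamped <- rep(FALSE, n)
    for (w in 1:52) {
      raw <- state + flux[, w]
      state <- clamp(raw, 0, cfg$ceiling)
      clamped <- clamped | (raw != state)
      sm[, w] <- state
    }
    if (max(abs(sm - prev)) < 1e-6) { converged <- TRUE; break }
    # Cells that never touched a clamp drift linearly by `net` per year;
    # fast-forward whole years analytically until just before a bound.
    net <- state - start
    ff <- !clamped & abs(net) > 1e-12
    if (any(ff)) {
      dist <- ifelse(net[ff] > 0, cfg$ceiling - state[ff], state[ff])
      state[ff] <- state[ff] + floor(dist / abs(net[ff])) * net[ff]
    }
  }
  if (!converged) {
    ecx_warn("soil-moisture cycle not converged after ", cfg$spinup_years,
             " spin-up years; returning last cycle")
  }
  if (vec) as.vector(sm) else sm
}

#' Annual growth index
#'
#' `GI_A = 100 * mean_w(TI_w * MI_w)`: the annual average of the weekly
#' growth index, scaled to `[0, 100]`.
#'
#' @param TI,MI 52-length vectors (or n x 52 matrices) of weekly indices in
#'   `[0, 1]`.
#' @return `GI_A` in `[0, 100]` (vector of length n for matrix input).
#' @export
annual_growth_index <- function(TI, MI) {
  if (!identical(dim(TI), dim(MI)) || length(TI) != length(MI)) {
    ecx_stop("TI and MI must have identical shape")
  }
  if (is.null(dim(TI))) {
    if (length(TI) != 52L) ecx_stop("weekly index series must have 52 weeks")
    100 * mean(TI * MI)
  } else {
    if (ncol(TI) != 52L) ecx_stop("weekly index series must have 52 weeks")
    100 * rowMeans(TI * MI)
  }
}

# Shared accumulation for the three stresses. Magnitude mode weights each
# week by the threshold exceedance (deg C weeks); occupancy mode counts
# weeks beyond the threshold. Result is percent, capped at 100.
accumulate_stress <- function(deficit, rate, mode) {
  contrib <- switch(mode,
    magnitude = pmax(0, deficit),
    occupancy = (deficit > 0) * 1,
    ecx_stop("stress mode must be 'magnitude' or 'occupancy'")
  )
  dim(contrib) <- dim(deficit)
  tot <- if (is.null(dim(contrib))) sum(contrib) else rowSums(contrib)
  pmin(100, 100 * abs(rate) * tot)
}

#' Annual cold stress
#'
#' `CS = min(100, 100 * |THCS| * sum_w max(0, TTCS - tmin_w))`: weekly
#' minimum-temperature shortfalls below the cold-stress threshold,
#' accumulated at the weekly rate and expressed in percent.
#'
#' @param tmin 52-length vector or n x 52 matrix of weekly minimum
#'   temperatures, deg C.
#' @param p `ecx_params`.
#' @param mode `"magnitude"` (default: weight by deg C shortfall) or
#'   `"occupancy"` (count weeks below threshold).
#' @return CS in `[0, 100]`.
#' @export
cold_stress <- function(tmin, p, mode = "magnitude") {
  accumulate_stress(p$TTCS - tmin, p$THCS, mode)
}

#' Annual heat stress
#'
#' `HS = min(100, 100 * THHS * sum_w max(0, tmax_w - TTHS))`.
#'
#' @param tmax 52-length vector or n x 52 matrix of weekly maximum
#'   temperatures, deg C.
#' @inheritParams cold_stress
#' @return HS in `[0, 100]`.
#' @export
heat_stress <- function(tmax, p, mode = "magnitude") {
  accumulate_stress(tmax - p$TTHS, p$THHS, mode)
}

#' Annual dry stress
#'
#' `DS = min(100, 100 * |HDS| * #\{w : SM_w < SMDS\})`: occupancy-weighted by
#' default because soil-moisture deficits are bounded in `[0, SMDS]`,
#' unlike the unbounded temperature exceedances.
#'
#' @param sm 52-length vector or n x 52 matrix of weekly soil moisture.
#' @param p `ecx_params`.
#' @param mode `"occupancy"` (default) or `"magnitude"`.
#' @return DS in `[0, 100]`.
#' @export
dry_stress <- function(sm, p, mode = "occupancy") {
  accumulate_stress(p$SMDS - sm, p$HDS, mode)
}

#' Annual degree-days above the developmental base temperature
#'
#' `DD = sum_w 7 * max(0, tmean_w - DV0)`, in deg C days. Population
#' persistence requires `DD >= PPD` (1517 deg C days for the default
#' parameter set); the ecoclimatic index is forced to 0 where the thermal
#' sum is insufficient for one generation per year.
#'
#' @param tmean 52-length vector or n x 52 matrix of weekly mean
#'   temperatures, deg C.
#' @param p `ecx_params`.
#' @return DD (deg C days), vector of length n for matrix input.
#' @export
degree_days <- function(tmean, p) {
  exc <- pmax(0, tmean - p$DV0)
  dim(exc) <- dim(tmean)
  if (is.null(dim(exc))) 7 * sum(exc) else 7 * rowSums(exc)
}

#' Ecoclimatic index from annual components
#'
#' `EI = GI_A * (1 - CS/100) * (1 - HS/100) * (1 - DS/100)`, set to 0
#' wherever `DD < PPD` (degree-day persistence gate), clamped to
#' `[0, 100]`.
#'
#' @param GI_A annual growth index in `[0, 100]`.
#' @param CS,HS,DS accumulated stresses in `[0, 100]`.
#' @param DD annual degree-days above `DV0`.
#' @param p `ecx_params`.
#' @return EI in `[0, 100]`; vectorised over cells.
#' @export
ecoclimatic_index <- function(GI_A, CS, HS, DS, DD, p) {
  SI <- (1 - CS / 100) * (1 - HS / 100) * (1 - DS / 100)
  EI <- GI_A * SI
  EI[DD < p$PPD] <- 0
  clamp(EI, 0, 100)
}

#' Three-class suitability label
#'
#' `EI = 0` is unsuitable, `0 < EI < 30` low suitability, `EI >= 30` high
#' suitability (the boundary value 30 is assigned to "high" so the three
#' classes partition `[0, 100]`).
#'
#' @param EI ecoclimatic index values in `[0, 100]`.
#' @return factor with levels `unsuitable`, `low`, `high`.
#' @export
classify_ei <- function(EI) {
  if (any(is.na(EI)) || any(EI < 0 | EI > 100)) {
    ecx_stop("EI must lie in [0, 100]")
  }
  cl <- ifelse(EI == 0, "unsuitable", ifelse(EI < 30, "low", "high"))
  factor(cl, levels = EI_CLASSES)
}

class_code <- function(cl) as.integer(factor(cl, levels = EI_CLASSES)) - 1L

# Weekly climate + converged soil moisture, computed once per grid.
# Soil moisture depends only on climate and the bucket config, never on the
# species parameters, so sensitivity runs reuse this across all 30
# perturbations.
prepare_climate <- function(grid, cfg = soil_moisture_config()) {
  wk <- monthly_to_weekly(grid)
  wk$sm <- soil_moisture_series(wk$precip, wk$tmean, wk$rh, cfg)
  wk
}

# Evaluate a parameter vector against prepared weekly climate.
evaluate_params <- function(wk, p, stress_modes = list()) {
  tmode <- stress_modes$temperature %||% "magnitude"
  dmode <- stress_modes$dry %||% "occupancy"
  TI <- temperature_index(wk$tmean, p)
  MI <- moisture_index(wk$sm, p)
  GI_A <- annual_growth_index(TI, MI)
  CS <- cold_stress(wk$tmin, p, tmode)
  HS <- heat_stress(wk$tmax, p, tmode)
  DS <- dry_stress(wk$sm, p, dmode)
  DD <- degree_days(wk$tmean, p)
  EI <- ecoclimatic_index(GI_A, CS, HS, DS, DD, p)
  df <- data.frame(
    lat = wk$cells$lat, lon = wk$cells$lon,
    EI = EI, class = classify_ei(EI),
    GI_A = GI_A, CS = CS, HS = HS, DS = DS, DD = DD,
    land = wk$cells$land
  )
  structure(df, class = c("ecx_map", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the ecoclimatic-index engine over a climate grid
#'
#' Per cell: interpolate the monthly normals to 52 weeks, spin up the
#' soil-moisture bucket, compute weekly temperature and moisture indices,
#' accumulate cold/heat/dry stress and degree-days, and combine into the
#' annual EI and its suitability class. Cells are independent; output rows
#' match the grid's cell order.
#'
#' @param grid `ecx_climate` monthly grid.
#' @param p `ecx_params` (defaults to the *U. panicoides* adjusted set).
#' @param cfg `ecx_sm_config` soil-moisture configuration.
#' @param stress_modes optional list overriding accumulation weighting, e.g.
#'   `list(temperature = "occupancy", dry = "magnitude")`.
#' @return `ecx_map`: data.frame with `lat, lon, EI, class, GI_A, CS, HS,
#'   DS, DD, land`.
#' @examples
#' g <- generate_climate_grid(climate_spec(n_lat = 6, n_lon = 6, seed = 1))
#' m <- run_grid(g)
#' table(m$class)
#' @export
run_grid <- function(grid, p = species_params(), cfg = soil_moisture_config(),
                     stress_modes = list()) {
  stopifnot(inherits(grid, "ecx_climate"))
  validate_params(p)
  wk <- prepare_climate(grid, cfg)
  evaluate_params(wk, p, stress_modes)
}
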