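# Seeded synthetic climate grids and occurrence samples with the structure
# the analysis assumes: a latitudinal temperature gradient, hemispheric
# seasonality, banded precipitation, and occurrences concentrated in
# climatically suitable cells. Qualitative structure only -- no attempt to
# match real gridded-climatology marginals.

#' Specification for a synthetic monthly climate grid
#'
#' Monthly mean temperature per cell and month is
#' `equator_mean_temp - lapse_per_degree_lat * |lat| +
#' seasonal_amplitude_per_degree_lat * |lat| * cos(2 * pi * (m - peak)/12)`
#' with the warmest month `peak` in July for the northern hemisphere and
#' January for the southern, so seasonal phase flips across the equator and
#' the seasonal cycle vanishes at the equator. Gaussian noise (sd
#' `noise_sd`) is added to the monthly mean only; `tmin`/`tmax` are then
#' derived as mean -/+ half the diurnal range, which guarantees
#' `tmin <= tmax`. Precipitation follows three latitude bands (wet tropics,
#' dry subtropics, moderate temperate); humidity is `humidity_base` +/- a
#' fixed morning/afternoon offset.
#'
#' @param n_lat,n_lon grid rows (>= 2) and columns (>= 1); cells sit at
#'   band centres.
#' @param lat_range length-2 latitude extent within `[-90, 90]`.
#' @param equator_mean_temp annual-mean temperature at the equator, deg C.
#' @param lapse_per_degree_lat cooling per degree of absolute latitude,
#'   deg C.
#' @param seasonal_amplitude_per_degree_lat seasonal half-amplitude gain per
#'   degree of absolute latitude, deg C.
#' @param diurnal_range `tmax - tmin`, deg C (>= 0).
#' @param precip_levels named mm/month levels for the `wet`, `dry` and
#'   `moderate` bands (`|lat| < 15`, `15-35`, `> 35` degrees).
#' @param humidity_base mean relative-humidity fraction.
#' @param noise_sd temperature noise standard deviation, deg C (>= 0).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   grids.
#' @return `ecx_climate_spec` object.
#' @export
climate_spec <- function(n_lat = 36, n_lon = 72, lat_range = c(-90, 90),
                         equator_mean_temp = 27, lapse_per_degree_lat = 0.55,
                         seasonal_amplitude_per_degree_lat = 0.35,
                         diurnal_range = 10,
                         precip_levels = c(wet = 150, dry = 20, moderate = 60),
                         humidity_base = 0.7, noise_sd = 0.5, seed = 1) {
  check_number(n_lat, "n_lat", lo = 2)
  check_number(n_lon, "n_lon", lo = 1)
  if (length(lat_range) != 2L || any(lat_range < -90 | lat_range > 90) ||
      lat_range[1] >= lat_range[2]) {
    ecx_stop("lat_range must be an increasing pair within [-90, 90]")
  }
  check_number(diurnal_range, "diurnal_range", lo = 0)
  check_number(noise_sd, "noise_sd", lo = 0)
  check_number(humidity_base, "humidity_base", lo = 0, hi = 1)
  if (!all(c("wet", "dry", "moderate") %in% names(precip_levels))) {
    ecx_stop("precip_levels needs named levels wet, dry, moderate")
  }
  if (any(precip_levels < 0)) ecx_stop("precip_levels must be >= 0")
  check_number(seed, "seed")
  structure(
    list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
         lat_range = as.numeric(lat_range),
         equator_mean_temp = equator_mean_temp,
         lapse_per_degree_lat = lapse_per_degree_lat,
         seasonal_amplitude_per_degree_lat = seasonal_amplitude_per_degree_lat,
         diurnal_range = diurnal_range,
         precip_levels = precip_levels[c("wet", "dry", "moderate")],
         humidity_base = humidity_base, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "ecx_climate_spec"
  )
}

#' Generate a seeded synthetic climate grid
#'
#' @param spec `ecx_climate_spec`.
#' @return `ecx_climate` monthly grid (see [climate_grid()]).
#' @examples
#' g <- generate_climate_grid(climate_spec(n_lat = 4, n_lon = 4, seed = 7))
#' head(g)
#' @export
generate_climate_grid <- function(spec = climate_spec()) {
  stopifnot(inherits(spec, "ecx_climate_spec"))
  lat_step <- diff(spec$lat_range) / spec$n_lat
  lats <- spec$lat_range[1] + (seq_len(spec$n_lat) - 0.5) * lat_step
  lons <- -180 + (seq_len(spec$n_lon) - 0.5) * 360 / spec$n_lon
  cells <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
  months <- 1:12
  df <- merge(cells, data.frame(month = months))
  # warmest month: July (7) north of the equator, January (1) south
  peak <- ifelse(df$lat >= 0, 7, 1)
  seasonal <- spec$seasonal_amplitude_per_degree_lat * abs(df$lat) *
    cos(2 * pi * (df$month - peak) / 12)
  tmean <- spec$equator_mean_temp -
    spec$lapse_per_degree_lat * abs(df$lat) + seasonal
  if (spec$noise_sd > 0) {
    tmean <- tmean + with_seed(spec$seed, stats::rnorm(nrow(df), 0, spec$noise_sd))
  }
  df$tmin <- tmean - spec$diurnal_range / 2
  df$tmax <- tmean + spec$diurnal_range / 2
  band <- ifelse(abs(df$lat) < 15, "wet",
                 ifelse(abs(df$lat) <= 35, "dry", "moderate"))
  df$precip <- unname(spec$precip_levels[band])
  df$rh09 <- clamp(spec$humidity_base + 0.05, 0, 1)
  df$rh15 <- clamp(spec$humidity_base - 0.05, 0, 1)
  climate_grid(df[c("lat", "lon", "month", "tmin", "tmax", "precip",
                    "rh09", "rh15")])
}

#' Specification for sampling synthetic occurrence points
#'
#' Non-contaminant points are drawn over cells with probability proportional
#' to `EI^suitability_weighting`; a `contamination_fraction` of points is
#' drawn uniformly over land cells regardless of suitability (emulating
#' database noise). Points are jittered within their cell by up to
#' `jitter_km`. The default 730 points mirrors a typical unthinned
#' occurrence download for a widespread invasive grass.
#'
#' @param n_points number of points (>= 0).
#' @param suitability_weighting exponent on EI in the sampling weights.
#' @param contamination_fraction fraction in `[0, 1]` sampled uniformly.
#' @param jitter_km within-cell positional jitter, km (>= 0).
#' @param seed integer RNG seed.
#' @return `ecx_occ_spec` object.
#' @export
occurrence_spec <- function(n_points = 730, suitability_weighting = 1,
                            contamination_fraction = 0.02, jitter_km = 5,
                            seed = 1) {
  check_number(n_points, "n_points", lo = 0)
  check_number(suitability_weighting, "suitability_weighting", lo = 0)
  check_number(contamination_fraction, "contamination_fraction", lo = 0, hi = 1)
  check_number(jitter_km, "jitter_km", lo = 0)
  check_number(seed, "seed")
  structure(
    list(n_points = as.integer(n_points),
         suitability_weighting = suitability_weighting,
         contamination_fraction = contamination_fraction,
         jitter_km = jitter_km, seed = as.integer(seed)),
    class = "ecx_occ_spec"
  )
}

#' Sample synthetic occurrence points from a suitability map
#'
#' @param map `ecx_map` suitability map with at least one `EI > 0` land
#'   cell when `contamination_fraction < 1`.
#' @param spec `ecx_occ_spec`.
#' @param species species name recorded in the output.
#' @return `ecx_occurrences`: data.frame with columns `species`, `lat`,
#'   `lon`.
#' @export
sample_occurrences <- function(map, spec = occurrence_spec(),
                               species = "Urochloa panicoides") {
  stopifnot(inherits(map, "ecx_map"), inherits(spec, "ecx_occ_spec"))
  land <- which(map$land)
  if (!length(land)) ecx_stop("map has no land cells")
  if (spec$n_points == 0L) {
    return(occurrence_set(data.frame(species = character(), lat = numeric(),
                                     lon = numeric()),
                          provenance = "synthetic"))
  }
  w <- map$EI[land]^spec$suitability_weighting
  w[map$EI[land] == 0] <- 0   # 0^0 guard: zero-EI cells never weighted in
  if (all(w == 0) && spec$contamination_fraction < 1) {
    ecx_stop("all-zero EI map: cannot sample suitability-weighted points",
             class = "ecx_unsampleable_error")
  }
  lat_sp <- median(diff(sort(unique(map$lat))))
  lon_sp <- median(diff(sort(unique(map$lon))))
  if (!is.finite(lat_sp)) lat_sp <- 1
  if (!is.finite(lon_sp)) lon_sp <- 1
  with_seed(spec$seed, {
    n_cont <- stats::rbinom(1, spec$n_points, spec$contamination_fraction)
    n_suit <- spec$n_points - n_cont
    idx <- c(
      if (n_suit > 0) sample(land, n_suit, replace = TRUE, prob = w),
      if (n_cont > 0) sample(land, n_cont, replace = TRUE)
    )
    lat <- map$lat[idx]
    lon <- map$lon[idx]
    # within-cell jitter, capped at both jitter_km and the half cell spacing
    dlat <- pmin(spec$jitter_km / 111.32, lat_sp / 2)
    dlon <- pmin(spec$jitter_km / (111.32 * pmax(cos(lat * pi / 180), 0.05)),
                 lon_sp / 2)
    lat <- clamp(lat + stats::runif(length(idx), -1, 1) * dlat, -90, 90)
    lon <- lon + stats::runif(length(idx), -1, 1) * dlon
    lon <- ((lon + 180) %% 360) - 180
    occurrence_set(data.frame(species = species, lat = lat, lon = lon),
                   provenance = "synthetic")
  })
}
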