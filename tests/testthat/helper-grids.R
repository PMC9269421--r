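# Programmatic climate fixtures. All fixtures are built in code; no files.

# A grid of n_cells constant-climate cells (same value every month).
constant_grid <- function(tmean = 30, precip = 150, rh = 0.7,
                          diurnal = 10, lats = 0, lons = 0) {
  cells <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
  df <- merge(cells, data.frame(month = 1:12))
  df$tmin <- tmean - diurnal / 2
  df$tmax <- tmean + diurnal / 2
  df$precip <- precip
  df$rh09 <- rh + 0.05
  df$rh15 <- rh - 0.05
  climate_grid(df)
}

# Cold-limited latitudinal gradient: warm wet days but increasingly severe
# night frost poleward (large diurnal range), so cold stress is the binding
# constraint over part of the gradient.
cold_limited_grid <- function(n_lat = 36, n_lon = 4) {
  lats <- seq(1, 71, length.out = n_lat)
  lons <- seq(-10, 10, length.out = n_lon)
  cells <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
  df <- merge(cells, data.frame(month = 1:12))
  tmean <- 28 - 0.3 * df$lat          # annual constant, no seasonal cycle
  df$tmin <- tmean - 15               # frosty nights
  df$tmax <- tmean + 15
  df$precip <- 150
  df$rh09 <- 0.75
  df$rh15 <- 0.65
  climate_grid(df)
}

# Moisture-limited tropics band: warm everywhere, precipitation declining
# along the gradient through the dry-stress region.
moisture_limited_grid <- function(n = 30) {
  lats <- seq(-10, 10, length.out = n)
  df <- merge(data.frame(lat = lats, lon = 0),
              data.frame(month = 1:12))
  df$tmin <- 22
  df$tmax <- 32
  # 60 mm/month down to near zero across the band
  df$precip <- pmax(0, 60 * (1 - (df$lat + 10) / 20))
  df$rh09 <- 0.6
  df$rh15 <- 0.5
  climate_grid(df)
}
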