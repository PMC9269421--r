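# Independent scalar reference implementations used as oracles. These are
# deliberately written as plain per-cell / per-week loops with if/else
# logic, sharing no code with the vectorised package internals.

oracle_trapezoid <- function(x, a, b, c, d) {
  if (x <= a || x >= d) return(0)
  if (x >= b && x <= c) return(1)
  if (x < b) (x - a) / (b - a) else (d - x) / (d - c)
}

# circular linear interpolation of 12 monthly midpoint values to 52 weeks
oracle_weekly_interp <- function(monthly) {
  year <- 52 * 7
  mmid <- ((1:12) - 0.5) * year / 12
  out <- numeric(52)
  for (w in 1:52) {
    t <- (w - 0.5) * 7
    if (t < mmid[1]) {
      lo <- 12; hi <- 1; t0 <- mmid[12] - year; t1 <- mmid[1]
    } else if (t >= mmid[12]) {
      lo <- 12; hi <- 1; t0 <- mmid[12]; t1 <- mmid[1] + year
    } else {
      lo <- max(which(mmid <= t)); hi <- lo + 1
      t0 <- mmid[lo]; t1 <- mmid[hi]
    }
    f <- (t - t0) / (t1 - t0)
    out[w] <- monthly[lo] * (1 - f) + monthly[hi] * f
  }
  out
}

# naive bucket spin-up: plain repeated years, no acceleration
oracle_soil_moisture <- function(precip_w, tmean_w, rh_w, cfg,
                                 max_years = 5000) {
  state <- cfg$initial_sm
  sm <- numeric(52)
  for (yr in 1:max_years) {
    prev <- sm
    for (w in 1:52) {
      e <- cfg$et_coefficient * max(0, tmean_w[w]) * (1.05 - rh_w[w])
      state <- state + (precip_w[w] - e) / cfg$capacity
      if (state < 0) state <- 0
      if (state > cfg$ceiling) state <- cfg$ceiling
      sm[w] <- state
    }
    if (max(abs(sm - prev)) < 1e-6) break
  }
  sm
}

# full scalar pipeline for one cell given its 12 monthly rows
oracle_cell <- function(rows, p, cfg) {
  rows <- rows[order(rows$month), ]
  tmin_w <- oracle_weekly_interp(rows$tmin)
  tmax_w <- oracle_weekly_interp(rows$tmax)
  tmean_w <- (tmin_w + tmax_w) / 2
  rh_w <- (oracle_weekly_interp(rows$rh09) + oracle_weekly_interp(rows$rh15)) / 2
  pw <- oracle_weekly_interp(rows$precip * 12 / 52)
  annual <- sum(rows$precip)
  if (sum(pw) > 0) pw <- pw * annual / sum(pw)
  sm_w <- oracle_soil_moisture(pw, tmean_w, rh_w, cfg)

  gi <- 0; cs <- 0; hs <- 0; ds <- 0; dd <- 0
  for (w in 1:52) {
    ti <- oracle_trapezoid(tmean_w[w], p$DV0, p$DV1, p$DV2, p$DV3)
    mi <- oracle_trapezoid(sm_w[w], p$SM0, p$SM1, p$SM2, p$SM3)
    gi <- gi + ti * mi
    if (tmin_w[w] < p$TTCS) cs <- cs + (p$TTCS - tmin_w[w])
    if (tmax_w[w] > p$TTHS) hs <- hs + (tmax_w[w] - p$TTHS)
    if (sm_w[w] < p$SMDS) ds <- ds + 1
    if (tmean_w[w] > p$DV0) dd <- dd + 7 * (tmean_w[w] - p$DV0)
  }
  GI_A <- 100 * gi / 52
  CS <- min(100, 100 * abs(p$THCS) * cs)
  HS <- min(100, 100 * p$THHS * hs)
  DS <- min(100, 100 * abs(p$HDS) * ds)
  SI <- (1 - CS / 100) * (1 - HS / 100) * (1 - DS / 100)
  EI <- if (dd < p$PPD) 0 else GI_A * SI
  EI <- min(100, max(0, EI))
  c(EI = EI, GI_A = GI_A, CS = CS, HS = HS, DS = DS, DD = dd)
}

oracle_run_grid <- function(grid, p, cfg) {
  df <- as.data.frame(grid)
  key <- paste(df$lat, df$lon)
  cells <- unique(df[c("lat", "lon")])
  out <- t(vapply(seq_len(nrow(cells)), function(i) {
    rows <- df[df$lat == cells$lat[i] & df$lon == cells$lon[i], ]
    oracle_cell(rows, p, cfg)
  }, c(EI = 0, GI_A = 0, CS = 0, HS = 0, DS = 0, DD = 0)))
  cbind(cells, as.data.frame(out))
}

# hand-rolled haversine, km (mean Earth radius 6371 km)
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# brute-force greedy thinning over points sorted by (lat, lon, species)
oracle_thin <- function(df, radius_km) {
  df <- df[order(df$lat, df$lon, df$species), , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (oracle_haversine_km(df$lat[i], df$lon[i],
                              df$lat[j], df$lon[j]) <= radius_km) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  df[keep, , drop = FALSE]
}
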