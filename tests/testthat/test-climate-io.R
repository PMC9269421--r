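test_that("climate CSV round-trips through write and read", {
  g <- generate_climate_grid(climate_spec(n_lat = 4, n_lon = 4, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_climate_csv(g, f, seed = 2)
  g2 <- read_climate_csv(f)
  expect_equal(as.data.frame(g2), as.data.frame(g), tolerance = 1e-12)
})

test_that("malformed climate inputs raise structured errors", {
  g <- as.data.frame(generate_climate_grid(climate_spec(n_lat = 2, n_lon = 2,
                                                        seed = 1)))
  bad <- g
  bad$tmin[5] <- bad$tmax[5] + 3
  expect_error(climate_grid(bad),
               paste0("tmin > tmax at cell lat=", bad$lat[5]))

  expect_error(climate_grid(g[-3]), "missing column")
  expect_error(climate_grid(rbind(g, g[1, ])), "duplicate cell-month")
  expect_error(climate_grid(g[0, ]), "no rows")
  expect_error(climate_grid(g[-1, ]), "exactly 12 months")

  nag <- g
  nag$precip[2] <- NA
  expect_error(climate_grid(nag), "missing values")

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("lat,lon,month,tmin,tmax,precip,rh09,rh15", f)
  expect_error(read_climate_csv(f), "empty data section")
})

test_that("percent-style humidity is auto-detected", {
  g <- as.data.frame(constant_grid(tmean = 25))
  g$rh09 <- 75
  g$rh15 <- 65
  g2 <- climate_grid(g)
  expect_equal(unique(g2$rh09), 0.75)
  expect_equal(unique(g2$rh15), 0.65)
})

test_that("weekly interpolation preserves constants, totals and means", {
  g <- constant_grid(tmean = 18, precip = 75, rh = 0.6)
  wk <- monthly_to_weekly(g)
  expect_equal(ncol(wk$tmean), 52L)
  expect_equal(as.vector(wk$tmean), rep(18, 52))
  expect_equal(as.vector(wk$rh), rep(0.6, 52))
  # constant 75 mm/month must spread to 75 * 12 / 52 mm/week
  expect_equal(as.vector(wk$precip), rep(75 * 12 / 52, 52))

  # seasonal grid: annual precip conserved, weekly/monthly means agree
  g2 <- generate_climate_grid(climate_spec(n_lat = 8, n_lon = 4, seed = 3))
  wk2 <- monthly_to_weekly(g2)
  ann_monthly <- aggregate(precip ~ lat + lon, as.data.frame(g2), sum)
  ann_monthly <- ann_monthly[order(ann_monthly$lat, ann_monthly$lon), ]
  ord <- order(wk2$cells$lat, wk2$cells$lon)
  expect_equal(rowSums(wk2$precip)[ord], ann_monthly$precip,
               tolerance = 0.005, ignore_attr = TRUE)

  g2$tmean <- (g2$tmin + g2$tmax) / 2
  mon_mean <- aggregate(tmean ~ lat + lon, as.data.frame(g2), mean)
  mon_mean <- mon_mean[order(mon_mean$lat, mon_mean$lon), ]
  expect_equal(rowMeans(wk2$tmean)[ord], mon_mean$tmean,
               tolerance = 0.01, ignore_attr = TRUE)
  expect_true(all(wk2$tmin <= wk2$tmean & wk2$tmean <= wk2$tmax))
})

test_that("scenario transforms shift, scale, and compose as expected", {
  g <- generate_climate_grid(climate_spec(n_lat = 4, n_lon = 4, seed = 5))
  id <- apply_scenario(g, scenario_transform(0, 1, "id"))
  expect_equal(as.data.frame(id), as.data.frame(g))

  cs <- apply_scenario(g, scenario_transform(2.11, 0.86, "2100"))
  expect_equal(cs$tmin, g$tmin + 2.11)
  expect_equal(cs$tmax, g$tmax + 2.11)
  expect_equal(cs$precip, g$precip * 0.86)
  expect_equal(cs$rh09, g$rh09)
  expect_equal(cs[c("lat", "lon", "month")], g[c("lat", "lon", "month")])

  twice <- apply_scenario(apply_scenario(g, scenario_transform(1, 1)),
                          scenario_transform(1, 1))
  once <- apply_scenario(g, scenario_transform(2, 1))
  expect_equal(as.data.frame(twice), as.data.frame(once))

  # temperature shift commutes with weekly interpolation
  wk_shift <- monthly_to_weekly(apply_scenario(g, scenario_transform(3, 1)))
  wk_then <- monthly_to_weekly(g)
  expect_equal(wk_shift$tmean, wk_then$tmean + 3, tolerance = 1e-12)
  expect_equal(wk_shift$tmin, wk_then$tmin + 3, tolerance = 1e-12)
})

test_that("default projection scenarios scale the full-century change", {
  sc <- default_scenarios()
  expect_named(sc, c("2050", "2080", "2100"))
  expect_equal(sc[["2100"]]$delta_t, 2.11)
  expect_equal(sc[["2100"]]$precip_scale, 0.86)
  expect_equal(sc[["2050"]]$delta_t, 2.11 * 0.60)
  expect_equal(sc[["2080"]]$precip_scale, 1 - 0.14 * 0.84)
})

test_that("suitability CSV round-trips with class codebook 0/1/2", {
  map <- run_grid(generate_climate_grid(climate_spec(n_lat = 6, n_lon = 6,
                                                     seed = 1)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_suitability(map, f, seed = 1)
  raw <- utils::read.csv(f, comment.char = "#")
  expect_equal(raw$class_code,
               c(unsuitable = 0L, low = 1L, high = 2L)[raw$class],
               ignore_attr = TRUE)
  back <- read_suitability(f)
  expect_equal(back$EI, map$EI, tolerance = 1e-6)
  expect_equal(as.character(back$class), as.character(map$class))

  expect_error(write_suitability(map, f, format = "geotiff"),
               class = "ecx_unsupported_format")
})
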