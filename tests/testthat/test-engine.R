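p <- species_params()

test_that("temperature trapezoid is exact at breakpoints and midpoints", {
  expect_equal(temperature_index(c(4, 25, 35, 45), p), c(0, 1, 1, 0))
  expect_equal(temperature_index(14.5, p), (14.5 - 4) / (25 - 4))
  expect_equal(temperature_index(14.5, p), 0.5)
  expect_equal(temperature_index(40, p), (45 - 40) / (45 - 35))
  expect_equal(temperature_index(c(-20, 3.999, 45.001, 60), p), rep(0, 4))
  expect_equal(temperature_index(c(25 + 1e-9, 35 - 1e-9), p), c(1, 1))
})

test_that("moisture trapezoid is exact at breakpoints and midpoints", {
  expect_equal(moisture_index(c(0.1, 0.2, 8, 10), p), c(0, 1, 1, 0))
  expect_equal(moisture_index(0.15, p), 0.5)
  expect_equal(moisture_index(9, p), 0.5)
  expect_equal(moisture_index(c(0, 12), p), c(0, 0))
})

test_that("trapezoids are continuous piecewise-linear functions", {
  xs <- seq(-5, 50, by = 0.01)
  ti <- temperature_index(xs, p)
  expect_true(all(ti >= 0 & ti <= 1))
  expect_lt(max(abs(diff(ti))),
            0.01 / min(p$DV1 - p$DV0, p$DV3 - p$DV2) + 1e-9)
  # against the independent scalar implementation
  expect_equal(ti, vapply(xs, oracle_trapezoid, 0,
                          a = p$DV0, b = p$DV1, c = p$DV2, d = p$DV3))
})

test_that("soil-moisture bucket honours equilibrium, drainage, and clamps", {
  cfg <- soil_moisture_config()
  # zero net flux every week: stays at the initial value
  tmean <- rep(20, 52)
  rh <- rep(0.65, 52)
  e <- cfg$et_coefficient * 20 * (1.05 - 0.65)
  sm <- soil_moisture_series(rep(e, 52), tmean, rh, cfg)
  expect_equal(sm, rep(cfg$initial_sm, 52))

  # no rain, positive evapotranspiration: monotone non-increasing to 0
  sm2 <- soil_moisture_series(rep(0, 52), tmean, rh, cfg)
  expect_true(all(diff(sm2) <= 1e-12))
  expect_equal(sm2[52], 0)

  # deluge: capped at the ceiling
  sm3 <- soil_moisture_series(rep(1000, 52), tmean, rh, cfg)
  expect_equal(sm3, rep(cfg$ceiling, 52))

  # matrix and vector paths agree; matches the naive spin-up oracle
  precip <- 10 + 8 * sin(2 * pi * (1:52) / 52)
  smv <- soil_moisture_series(precip, tmean, rh, cfg)
  smm <- soil_moisture_series(rbind(precip, precip), rbind(tmean, tmean),
                              rbind(rh, rh), cfg)
  expect_equal(smm[1, ], smv)
  expect_equal(smv, oracle_soil_moisture(precip, tmean, rh, cfg),
               tolerance = 1e-8)

  # non-convergence within the spin-up budget warns and returns a cycle
  tiny <- soil_moisture_config(spinup_years = 1, initial_sm = 0)
  expect_warning(soil_moisture_series(precip, tmean, rh, tiny),
                 "not converged")
})

test_that("annual growth index averages the weekly TI x MI product", {
  ones <- rep(1, 52)
  expect_equal(annual_growth_index(ones, ones), 100)
  expect_equal(annual_growth_index(rep(0, 52), ones), 0)
  expect_equal(annual_growth_index(c(rep(1, 26), rep(0, 26)), ones), 50)
  expect_error(annual_growth_index(rep(1, 10), rep(1, 52)), "shape")
})

test_that("cold stress accumulates tmin shortfalls below TTCS", {
  expect_equal(cold_stress(rep(4, 52), p), 0)
  expect_equal(cold_stress(rep(10, 52), p), 0)
  # 10 weeks at -6 C: deficit 10 C each, rate 0.002
  tmin <- c(rep(-6, 10), rep(10, 42))
  expect_equal(cold_stress(tmin, p), 100 * 10 * 0.002 * 10)
  expect_equal(cold_stress(tmin, p), 20)
  expect_equal(cold_stress(rep(-50, 52), p), 100)
})

test_that("heat stress accumulates tmax excesses above TTHS", {
  expect_equal(heat_stress(rep(45, 52), p), 0)
  tmax <- c(rep(50, 5), rep(30, 47))
  expect_equal(heat_stress(tmax, p), 100 * 5 * 0.02 * 5)
  expect_equal(heat_stress(tmax, p), 50)
  expect_equal(heat_stress(rep(70, 52), p), 100)
})

test_that("dry stress counts weeks below SMDS at rate |HDS|", {
  expect_equal(dry_stress(rep(0.1, 52), p), 0)
  expect_equal(dry_stress(c(rep(0.05, 30), rep(1, 22)), p), 30)
  expect_equal(dry_stress(rep(0, 52), p), 52)  # full year, still below cap
  # magnitude mode remains available
  expect_equal(dry_stress(rep(0.05, 52), p, mode = "magnitude"),
               100 * 0.01 * 52 * 0.05)
})

test_that("degree-days gate persistence through PPD", {
  expect_equal(degree_days(rep(4, 52), p), 0)
  expect_equal(degree_days(rep(25, 52), p), 52 * 7 * 21)
  expect_gte(degree_days(rep(25, 52), p), p$PPD)
  expect_equal(degree_days(rep(8, 52), p), 52 * 7 * 4)
  expect_lt(degree_days(rep(8, 52), p), p$PPD)  # 1456 < 1517
})

test_that("ecoclimatic index combines growth, stress, and persistence", {
  expect_equal(ecoclimatic_index(100, 0, 0, 0, 5000, p), 100)
  expect_equal(ecoclimatic_index(0, 0, 0, 0, 5000, p), 0)
  expect_equal(ecoclimatic_index(80, 50, 0, 0, 5000, p), 40)
  expect_equal(ecoclimatic_index(80, 50, 0, 0, 1456, p), 0)   # DD < PPD
  expect_equal(ecoclimatic_index(c(80, 80), c(50, 0), c(0, 0), c(0, 0),
                                 c(5000, 1000), p), c(40, 0))
})

test_that("classification follows the 0 / 30 boundaries", {
  expect_equal(as.character(classify_ei(c(0, 15, 30, 29.999, 100))),
               c("unsuitable", "low", "high", "low", "high"))
  expect_error(classify_ei(-1), "EI")
  expect_error(classify_ei(101), "EI")
})

test_that("a constant-optimal cell scores EI = 100, frozen cells 0", {
  map <- run_grid(constant_grid(tmean = 30, precip = 150, rh = 0.7))
  expect_equal(map$EI, 100)
  expect_equal(as.character(map$class), "high")

  frozen <- run_grid(constant_grid(tmean = 0, precip = 150, rh = 0.7))
  expect_equal(frozen$EI, 0)
  expect_equal(as.character(frozen$class), "unsuitable")
})

test_that("more stress never raises suitability (rate monotonicity)", {
  g <- generate_climate_grid(climate_spec(n_lat = 10, n_lon = 6, seed = 8))
  base <- run_grid(g)
  for (pp in list(species_params(THCS = -0.004),
                  species_params(THHS = 0.04),
                  species_params(HDS = -0.02))) {
    harsher <- run_grid(g, pp)
    expect_true(all(harsher$EI <= base$EI + 1e-12))
  }
})

test_that("all indices stay within their bounds on random climates", {
  set.seed(42)
  for (i in 1:5) {
    g <- generate_climate_grid(climate_spec(
      n_lat = 6, n_lon = 6, noise_sd = 4,
      equator_mean_temp = runif(1, 10, 35),
      diurnal_range = runif(1, 0, 25), seed = i))
    m <- run_grid(g)
    expect_true(all(m$EI >= 0 & m$EI <= 100))
    expect_true(all(m$GI_A >= 0 & m$GI_A <= 100))
    expect_true(all(m$CS >= 0 & m$CS <= 100))
    expect_true(all(m$HS >= 0 & m$HS <= 100))
    expect_true(all(m$DS >= 0 & m$DS <= 100))
    expect_true(all(m$DD >= 0))
    expect_true(all(m$EI[m$GI_A == 0] == 0))
    expect_true(all(m$EI[m$DD < species_params()$PPD] == 0))
  }
})
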