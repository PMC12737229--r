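test_that("regime sequences follow the configured distribution and seed", {
  cfg <- scenario_config(n_days = 20, seed = 7,
                         regime_probs = c(local = 0, north = 1, west = 0,
                                          east = 0, south = 0))
  expect_equal(generate_regime_sequence(cfg), rep("north", 20))
  expect_identical(generate_regime_sequence(cfg),
                   generate_regime_sequence(cfg))
  expect_error(scenario_config(n_days = 0), "n_days")
  expect_error(scenario_config(n_days = 5,
                               regime_probs = c(local = .5, north = .6,
                                                west = 0, east = 0,
                                                south = 0)),
               "sum to 1")
})

test_that("ensembles have the standard structure and start at the receptor", {
  cfg <- scenario_config(n_days = 1, seed = 3)
  for (rg in c("local", "north", "south")) {
    e <- generate_ensemble(as.POSIXct("2024-01-05 06:00", tz = "UTC"), rg,
                           cfg)
    expect_equal(length(unique(e$member)), 27L)
    expect_equal(nrow(e), 27L * 25L)
    a0 <- e[e$age_h == 0L, ]
    expect_equal(a0$lat, rep(39.98, 27))
    expect_equal(a0$lon, rep(116.40, 27))
    expect_equal(sort(unique(e$age_h)), -24:0)
  }
})

test_that("jitter-free northerly kinematics match an independent great-circle oracle", {
  regs <- regime_defaults()
  regs$speed_m_s[regs$name == "north"] <- 8
  cfg <- scenario_config(n_days = 1, jitter_deg = 0, jitter_ens_deg = 0,
                         jitter_speed = 0, jitter_ens_speed = 0,
                         regimes = regs, seed = 1)
  e <- generate_ensemble(as.POSIXct("2024-01-01", tz = "UTC"), "north", cfg)
  p <- e[e$member == 1L & e$age_h == -24L, ]
  d <- haversine_m(39.98, 116.40, p$lat, p$lon)
  expect_equal(d, 8 * 86400, tolerance = 1e-6)      # 691.2 km upwind
  expect_equal(p$lon, 116.40, tolerance = 1e-6)     # due north
  expect_gt(p$lat, 39.98)
})

test_that("northerly endpoints stay north and local endpoints stay local", {
  cfg <- scenario_config(n_days = 1, seed = 21)
  set.seed(99)
  sect <- default_sectors()
  for (k in 1:10) {
    e <- generate_ensemble(as.POSIXct("2024-01-01", tz = "UTC"), "north",
                           cfg)
    old <- e[e$age_h == -24L, ]
    expect_true(all(old$lat > 39.98))
    l <- generate_ensemble(as.POSIXct("2024-01-01", tz = "UTC"), "local",
                           cfg)
    expect_true(all(classify_point(sect, l$lon, l$lat) == "local"))
  }
})

test_that("concentration series hit the regime means", {
  regs0 <- regime_defaults()
  regs0$pm25_sigma_log[] <- 0
  cfg <- scenario_config(n_days = 2, regimes = regs0, seed = 1)
  s <- generate_concentration_series(rep("south", 2), cfg)
  expect_equal(s$pm25, rep(61, 48))
  n <- generate_concentration_series(rep("north", 2), cfg)
  expect_equal(n$pm25, rep(17.7, 48))

  # Monte-Carlo moment recovery: 10^4 hours within 3% of the mean
  regs3 <- regime_defaults()
  regs3$pm25_sigma_log[] <- 0.3
  cfg3 <- scenario_config(n_days = 417, regimes = regs3, seed = 3)
  s3 <- generate_concentration_series(rep("south", 417), cfg3)
  expect_lt(abs(mean(s3$pm25[1:10000]) / 61 - 1), 0.03)
  # and under the default dispersions, for every regime
  for (rg in regime_defaults()$name) {
    cfgr <- scenario_config(n_days = 417, seed = 11)
    sr <- generate_concentration_series(rep(rg, 417), cfgr)
    mu <- regime_defaults()$pm25_mean[regime_defaults()$name == rg]
    expect_lt(abs(mean(sr$pm25[1:10000]) / mu - 1), 0.03)
  }
  regs_bad <- regime_defaults()
  regs_bad$pm25_mean[1] <- -1
  expect_error(scenario_config(n_days = 1, regimes = regs_bad),
               "pm25_mean")
})

test_that("meteorology series reproduce the regime means and respect bounds", {
  cfg0 <- scenario_config(n_days = 2, met_noise = c(ws = 0, rh = 0, t = 0,
                                                    p = 0), seed = 5)
  m_n <- generate_met_series(rep("north", 2), cfg0)
  expect_equal(m_n$ws, rep(3, 48))
  m_s <- generate_met_series(rep("south", 2), cfg0)
  expect_equal(m_s$rh, rep(55, 48))
  expect_equal(m_s$t, rep(6.8, 48))
  expect_equal(m_s$p, rep(999, 48))
  # clipping holds under absurd noise
  cfgN <- scenario_config(n_days = 5, met_noise = c(ws = 50, rh = 500,
                                                    t = 2, p = 3), seed = 8)
  mN <- generate_met_series(rep("south", 5), cfgN)
  expect_true(all(mN$rh >= 0 & mN$rh <= 100))
  expect_true(all(mN$ws >= 0))
})

test_that("hotspot concentrations are linear in the endpoint fraction", {
  cfg <- scenario_config(n_days = 1, seed = 2)
  # two endpoints: one in the rectangle, one outside -> fraction 1/2
  s <- mk_set(members = 1L, steps = 2L, dlat = 3)   # ages 0, -1 at 39.98, 42.98
  hot <- list(lon_range = c(116, 117), lat_range = c(39.5, 40.5),
              base = 10, strength = 80, noise_sd = 0)
  out <- generate_hotspot_series(s, hot, cfg)
  expect_equal(out$pm25, 10 + 80 * 0.5)
  # no endpoint inside -> base; all inside -> base + strength
  far <- list(lon_range = c(110, 111), lat_range = c(35, 36),
              base = 10, strength = 80, noise_sd = 0)
  expect_equal(generate_hotspot_series(s, far, cfg)$pm25, 10)
  wide <- list(lon_range = c(110, 119), lat_range = c(35, 43),
               base = 10, strength = 80, noise_sd = 0)
  expect_equal(generate_hotspot_series(s, wide, cfg)$pm25, 90)
  bad <- list(lon_range = c(100, 111), lat_range = c(35, 36),
              base = 10, strength = 80)
  expect_error(generate_hotspot_series(s, bad, cfg), "outside the analysis")
})

test_that("whole scenarios are reproducible from the seed", {
  cfg <- scenario_config(n_days = 2, seed = 123)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$regimes, b$regimes)
  expect_identical(a$concentrations$pm25, b$concentrations$pm25)
  expect_identical(a$trajectories$lat, b$trajectories$lat)
  expect_identical(a$met$ws, b$met$ws)
})
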