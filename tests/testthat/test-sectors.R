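test_that("the five default sectors tile the domain without overlap", {
  s <- default_sectors()
  expect_equal(nrow(s), 5L)
  expect_setequal(s$name, c("local", "west", "north", "east", "south"))
  # receptor falls in the local sector
  expect_equal(classify_point(s, 116.40, 39.98), "local")
  # rectangle arithmetic: areas sum to the domain, intersections are empty
  areas <- (s$lon_max - s$lon_min) * (s$lat_max - s$lat_min)
  expect_equal(sum(areas), 12 * 9)
  for (a in 1:4) for (b in (a + 1):5) {
    ov_lon <- min(s$lon_max[a], s$lon_max[b]) - max(s$lon_min[a], s$lon_min[b])
    ov_lat <- min(s$lat_max[a], s$lat_max[b]) - max(s$lat_min[a], s$lat_min[b])
    expect_true(ov_lon <= 0 || ov_lat <= 0)
  }
})

test_that("point classification is half-open and exclusive", {
  s <- default_sectors()
  expect_equal(classify_point(s, 116.0, 40.0), "local")
  expect_equal(classify_point(s, 115.3, 40.0), "local")  # closed lower edge
  expect_equal(classify_point(s, 121.0, 40.0), "outside")
  expect_equal(classify_point(s, 117.5, 40.0), "east")   # shared edge owner
  expect_equal(classify_point(s, 116.0, 39.4), "local")
  # random points in the domain always land in exactly one sector
  set.seed(31)
  lon <- runif(10000, 108, 120 - 1e-9)
  lat <- runif(10000, 34, 43 - 1e-9)
  hits <- vapply(s$name, function(nm)
    lon >= s$lon_min[s$name == nm] & lon < s$lon_max[s$name == nm] &
    lat >= s$lat_min[s$name == nm] & lat < s$lat_max[s$name == nm],
    logical(10000))
  expect_true(all(rowSums(hits) == 1L))
})

test_that("sector integrals of a uniform field recover area shares", {
  g <- make_grid(108, 34, 120, 43, 0.1)   # 0.1 divides every sector edge
  fake <- list(grid = g, conc = matrix(5, g$n_lon, g$n_lat))
  si <- sector_integrals(fake)
  s <- default_sectors()
  areas <- (s$lon_max - s$lon_min) * (s$lat_max - s$lat_min)
  expect_equal(si$share, areas / sum(areas), tolerance = 1e-12)
  expect_equal(sum(si$share), 1)

  # field defined only in the north sector
  fake2 <- fake
  sec <- matrix(classify_point(s, grid_centers(g)$lon[row(fake$conc)],
                               grid_centers(g)$lat[col(fake$conc)]),
                g$n_lon, g$n_lat)
  fake2$conc[sec != "north"] <- NA_real_
  si2 <- sector_integrals(fake2)
  expect_equal(si2$share[si2$sector == "north"], 1)
  fake3 <- fake
  fake3$conc[] <- NA_real_
  expect_error(sector_integrals(fake3), "no defined cells")
})

test_that("per-time fractions are normalised and find the obvious dominant", {
  # one ensemble fully inside the local sector
  s <- mk_set(members = 3L, steps = 5L, dlat = 0.02)
  t0 <- as.POSIXct("2024-01-01", tz = "UTC")
  conc <- data.frame(time = t0, pm25 = 50)
  f <- cwt(s, conc)
  for (mode in c("cwt", "count")) {
    fr <- timewise_fractions(f, weighting = mode)
    expect_equal(fr$local, 1)
    expect_equal(fr$dominant, "local")
    expect_false(fr$tie)
    cols <- c(attr(fr, "sectors"), "outside")
    expect_equal(rowSums(fr[, cols]), 1, ignore_attr = TRUE)
  }
})

test_that("exact ties are broken by the documented priority and flagged", {
  # one endpoint in the local sector, one in the south sector
  t0 <- as.POSIXct("2024-01-01", tz = "UTC")
  df <- data.frame(arrival_time = t0, member = 1L, age_h = c(0L, -1L),
                   lat = c(39.98, 39.0), lon = 116.40, height = 250)
  f <- cwt(traj_set(df), data.frame(time = t0, pm25 = 20))
  fr <- timewise_fractions(f, weighting = "count")
  expect_equal(fr$local, 0.5)
  expect_equal(fr$south, 0.5)
  expect_true(fr$tie)
  expect_equal(fr$dominant, "local")   # priority order
})

test_that("arrivals with no usable endpoint weight are flagged indeterminate", {
  s <- mk_set(members = 1L, steps = 3L)
  t0 <- as.POSIXct("2024-01-01", tz = "UTC")
  g <- make_grid(0, 0, 10, 10, 1)      # domain nowhere near the receptor
  f <- quiet(cwt(s, data.frame(time = t0, pm25 = 10), g))
  fr <- timewise_fractions(f, weighting = "cwt")
  expect_true(fr$indeterminate)
  expect_true(is.na(fr$dominant))
  expect_error(dominant_source_per_day(fr), "no determinate")
})

test_that("daily labels recover a known low-noise regime sequence", {
  cfg <- scenario_config(n_days = 10, jitter_deg = 8, jitter_ens_deg = 6,
                         seed = 5)
  sc <- simulate_scenario(cfg)
  f <- cwt(sc$trajectories, sc$concentrations)
  fr <- timewise_fractions(f, weighting = "count")
  d <- dominant_source_per_day(fr)
  expect_equal(nrow(d), 10L)
  expect_gte(mean(d$source == sc$regimes), 0.9)
  # day labels follow the mean fraction over the day's records
  m <- aggregate(fr[, attr(fr, "sectors")],
                 list(date = as.Date(fr$time, tz = "UTC")), mean)
  for (k in seq_len(nrow(d))) {
    v <- unlist(m[k, -1])
    expect_equal(unname(d$source[k]), names(v)[which.max(v)])
  }
})
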