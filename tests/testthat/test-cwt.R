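test_that("residence counts are exact, linear and conservative", {
  g <- make_grid(108, 34, 120, 43, 0.25)
  one <- mk_set(members = 1L, steps = 3L, dlat = 0.005) # 3 pts, one cell
  r1 <- residence_counts(one, g)
  expect_equal(sum(r1$n), 3L)
  expect_equal(max(r1$n), 3L)
  expect_equal(sum(r1$n > 0L), 1L)
  expect_equal(r1$outside, 0L)

  two <- mk_set(members = 2L, steps = 3L, dlat = 0.005) # identical paths
  r2 <- residence_counts(two, g)
  expect_equal(r2$n, 2L * r1$n)

  # conservation on a seeded synthetic set
  cfg <- scenario_config(n_days = 2, seed = 4)
  sc <- simulate_scenario(cfg)
  rs <- residence_counts(sc$trajectories, g)
  expect_equal(sum(rs$n) + rs$outside, nrow(sc$trajectories))
  expect_equal(sum(rs$tau$count), sum(rs$n))

  # indicator mode: at most 1 per trajectory and cell
  ri <- residence_counts(two, g, tau_mode = "indicator")
  expect_equal(max(ri$tau$count), 1L)
  expect_equal(max(ri$n), 2L)
})

test_that("the sparse-cell weighting function matches its published bins", {
  expect_identical(weight_factor(4, 1), 1.00)
  expect_identical(weight_factor(3, 1), 0.70)   # upper bound inclusive
  expect_identical(weight_factor(2, 1), 0.70)
  expect_identical(weight_factor(1.5, 1), 0.42) # upper bound inclusive
  expect_identical(weight_factor(1.2, 1), 0.42)
  expect_identical(weight_factor(1, 1), 0.05)   # n <= n_ave
  expect_identical(weight_factor(0.5, 1), 0.05)
  expect_equal(weight_factor(c(10, 2.4, 1.1, 0.2), 1),
               c(1.00, 0.70, 0.42, 0.05))
  expect_error(weight_factor(1, 0), "positive")
  expect_error(weight_factor(-1, 1), ">= 0")
})

test_that("the field is the residence-weighted mean of receptor concentrations", {
  t0 <- as.POSIXct("2024-01-01", tz = "UTC")
  # trajectory A: 1 endpoint in the receptor cell; B: 3 endpoints in it
  a <- data.frame(arrival_time = t0, member = 1L, age_h = 0L,
                  lat = 39.98, lon = 116.40, height = 250)
  b <- data.frame(arrival_time = t0 + 3600, member = 1L, age_h = c(0L, -1L, -2L),
                  lat = c(39.98, 39.90, 39.85), lon = 116.40, height = 250)
  s <- traj_set(rbind(a, b))
  conc <- data.frame(time = c(t0, t0 + 3600), pm25 = c(10, 30))
  g <- make_grid(108, 34, 120, 43, 0.25)

  f0 <- cwt(s, conc, g, weighted = FALSE)
  cell <- cell_index(g, 116.40, 39.98)
  expect_equal(f0$conc[cell[1] + 1, cell[2] + 1], (10 * 1 + 30 * 3) / 4)
  # with an all-cell mean the busy cell clears 3*n_ave and keeps weight 1
  fw <- cwt(s, conc, g, weighted = TRUE, nave_mode = "all")
  expect_equal(fw$conc[cell[1] + 1, cell[2] + 1], 25 * 1.00)
  # unvisited cells are undefined, not zero
  expect_true(is.na(f0$conc[1, 1]))

  # constant concentrations, weight off: every visited cell equals it
  concc <- data.frame(time = c(t0, t0 + 3600), pm25 = c(42, 42))
  fc <- cwt(s, concc, g, weighted = FALSE)
  expect_equal(unique(fc$conc[is.finite(fc$conc)]), 42)

  # a missing arrival concentration is an error that names the time
  expect_error(cwt(s, conc[1, ], g), "2024-01-01 01:00")
})

test_that("vectorised CWT equals the naive triple-loop oracle", {
  for (seed in 1:10) {
    inst <- random_cwt_instance(seed)
    weighted <- seed %% 2 == 0
    nave <- if (seed %% 3 == 0) "all" else "occupied"
    got <- quiet(cwt(inst$set, inst$conc, inst$grid, weighted = weighted,
                     nave_mode = nave))$conc
    want <- naive_cwt(inst$set, inst$conc, inst$grid, weighted = weighted,
                      nave_mode = nave)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("field values are bounded and invariant to trajectory order", {
  cfg <- scenario_config(n_days = 3, seed = 6)
  sc <- simulate_scenario(cfg)
  f <- cwt(sc$trajectories, sc$concentrations)
  arr <- traj_arrivals(sc$trajectories)
  cl <- sc$concentrations$pm25[match(as.numeric(arr),
                                     as.numeric(sc$concentrations$time))]
  ok <- is.finite(f$conc)
  expect_true(all(f$conc[ok] <= max(cl) + 1e-12))
  expect_true(all(f$conc[ok] >= min(cl) * 0.05 - 1e-12))

  perm <- sc$trajectories[sample(nrow(sc$trajectories)), ]
  fp <- cwt(traj_set(perm, check = FALSE), sc$concentrations)
  expect_equal(fp$conc, f$conc)
})

test_that("per-time slices preserve order and conserve endpoints", {
  cfg <- scenario_config(n_days = 1, seed = 9)
  sc <- simulate_scenario(cfg)
  f <- cwt(sc$trajectories, sc$concentrations)
  sl <- cwt_slices(f)
  expect_length(sl, length(f$arrivals))
  expect_equal(names(sl), format(f$arrivals, "%Y-%m-%d %H:%M", tz = "UTC"))
  expect_equal(sum(vapply(sl, nrow, integer(1))), nrow(sc$trajectories))
  expect_equal(unique(sl[[3]]$arrival_time), f$arrivals[3])
})

test_that("model methods expose the fitted field", {
  cfg <- scenario_config(n_days = 1, seed = 10)
  sc <- simulate_scenario(cfg)
  f <- cwt(sc$trajectories, sc$concentrations)
  expect_s3_class(f, "cwt")
  expect_output(print(f), "Concentration-weighted")
  expect_equal(dim(coef(f)), c(48L, 36L))
  # predict returns the cell value at the receptor and NA off-domain
  cell <- cell_index(f$grid, 116.40, 39.98)
  expect_equal(predict(f, data.frame(lon = 116.40, lat = 39.98)),
               f$conc[cell[1] + 1, cell[2] + 1])
  expect_true(is.na(predict(f, data.frame(lon = 150, lat = 10))))
  s <- summary(f)
  expect_s3_class(s, "summary.cwt")
  expect_output(print(s), "sector shares")
  expect_equal(nrow(cwt_export(f)), 48L * 36L)
})
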