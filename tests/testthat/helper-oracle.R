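# Independent brute-force oracles and fixture builders. These deliberately
# re-derive everything from first principles (triple loops, explicit
# formulas) and never call the vectorised implementation paths they check.

# great-circle distance on the sphere used by the generator (haversine)
haversine_m <- function(lat1, lon1, lat2, lon2, R = 6378137) {
  tor <- pi / 180
  2 * R * asin(sqrt(sin((lat2 - lat1) * tor / 2)^2 +
                      cos(lat1 * tor) * cos(lat2 * tor) *
                        sin((lon2 - lon1) * tor / 2)^2))
}

naive_weight <- function(n, nave) {
  if (n > 3 * nave) 1.00
  else if (n > 1.5 * nave) 0.70
  else if (n > nave) 0.42
  else 0.05
}

# naive triple-loop CWT: loop trajectories to grid tau, loop cells for the
# weighted mean
naive_cwt <- function(set, conc, grid, weighted = TRUE,
                      nave_mode = "occupied") {
  key <- paste(as.numeric(set$arrival_time), set$member)
  trajs <- unique(key)
  M <- length(trajs)
  tau <- array(0L, c(grid$n_lon, grid$n_lat, M))
  for (l in seq_len(M)) {
    pts <- set[key == trajs[l], , drop = FALSE]
    for (r in seq_len(nrow(pts))) {
      i <- floor((pts$lon[r] - grid$lon_min) / grid$cell_size)
      j <- floor((pts$lat[r] - grid$lat_min) / grid$cell_size)
      if (i >= 0 && i < grid$n_lon && j >= 0 && j < grid$n_lat)
        tau[i + 1, j + 1, l] <- tau[i + 1, j + 1, l] + 1L
    }
  }
  arr_of <- as.numeric(vapply(strsplit(trajs, " "), `[`, "", 1L))
  Cl <- conc$pm25[match(arr_of, as.numeric(conc$time))]
  n <- apply(tau, c(1, 2), sum)
  nave <- if (nave_mode == "occupied") mean(n[n > 0]) else mean(n)
  C <- matrix(NA_real_, grid$n_lon, grid$n_lat)
  for (i in seq_len(grid$n_lon)) for (j in seq_len(grid$n_lat)) {
    den <- sum(tau[i, j, ])
    if (den > 0) {
      w <- if (weighted) naive_weight(n[i, j], nave) else 1
      C[i, j] <- sum(Cl * tau[i, j, ]) / den * w
    }
  }
  C
}

# random small CWT instance: trajectories scattered in and around a small
# grid, one concentration per arrival time
random_cwt_instance <- function(seed) {
  set.seed(seed)
  nlon <- sample(3:10, 1)
  nlat <- sample(3:10, 1)
  grid <- make_grid(0, 0, nlon * 0.25, nlat * 0.25, 0.25)
  M <- sample(2:20, 1)
  t0 <- as.POSIXct("2024-01-01", tz = "UTC")
  arr <- t0 + 3600 * sample(0:49, M, replace = TRUE)
  pts <- do.call(rbind, lapply(seq_len(M), function(l) {
    k <- sample(3:25, 1)
    data.frame(arrival_time = arr[l], member = l, age_h = 0:-(k - 1),
               lat = runif(k, -0.5, nlat * 0.25 + 0.5),
               lon = runif(k, -0.5, nlon * 0.25 + 0.5),
               height = 250)
  }))
  set <- traj_set(pts, receptor = c(lat = 0, lon = 0), check = FALSE)
  ua <- sort(unique(arr))
  conc <- data.frame(time = ua, pm25 = runif(length(ua), 5, 80))
  list(set = set, conc = conc, grid = grid)
}

# small hand-made trajectory set around the receptor; age-0 points exactly
# at the receptor, older points offset northward within/beyond its cell
mk_set <- function(members = 1L, steps = 2L,
                   arrival = as.POSIXct("2024-01-01", tz = "UTC"),
                   dlat = 0.02) {
  df <- expand.grid(age_h = 0:-(steps - 1L), member = seq_len(members))
  df$arrival_time <- arrival
  df$lat <- 39.98 - dlat * df$age_h
  df$lon <- 116.40
  df$height <- 250 - 10 * df$age_h
  traj_set(df)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
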