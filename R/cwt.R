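#' Grid trajectory residence counts
#'
#' Counts trajectory endpoints per grid cell: `tau[l, (i,j)]` is the number
#' of endpoints of trajectory `l` (one ensemble member at one arrival time)
#' in cell `(i, j)`, and `n[i, j] = sum_l tau` the cell total. Residence
#' time is represented by endpoint frequency (hourly endpoints, so counts
#' are proportional to time in cell). With `tau_mode = "indicator"` each
#' trajectory contributes at most 1 per cell instead.
#'
#' @param set A [traj_set()].
#' @param grid A [make_grid()] spec.
#' @param tau_mode `"endpoint"` (default) or `"indicator"`.
#' @return An object of class `residence_field`: list with `grid`, `n`
#'   (n_lon x n_lat integer matrix), `tau` (data frame `traj`, `i`, `j`,
#'   `count`), `n_ave` (mean count over occupied cells), `n_ave_all` (mean
#'   over all cells), `outside` (endpoints outside the domain),
#'   `n_endpoints`, `n_traj`.
#' @export
residence_counts <- function(set, grid,
                             tau_mode = c("endpoint", "indicator")) {
  stopifnot(inherits(set, "traj_set"), inherits(grid, "cwt_grid"))
  tau_mode <- match.arg(tau_mode)
  ij <- cell_index(grid, set$lon, set$lat)
  inside <- !is.na(ij[, 1L])
  traj <- paste(as.numeric(set$arrival_time), set$member)
  traj_id <- match(traj, unique(traj))
  cell <- ij[, 1L] + grid$n_lon * ij[, 2L]          # 0-based linear cell
  ncell <- grid$n_lon * grid$n_lat
  key <- (traj_id[inside] - 1) * ncell + cell[inside]
  if (tau_mode == "indicator") key <- unique(key)
  ord <- sort(key)
  r <- rle(ord)
  tau <- data.frame(traj = as.integer(r$values %/% ncell) + 1L,
                    i = as.integer(r$values %% ncell) %% grid$n_lon,
                    j = as.integer(r$values %% ncell) %/% grid$n_lon,
                    count = r$lengths)
  n <- matrix(0L, grid$n_lon, grid$n_lat)
  nm <- rowsum(tau$count, tau$i + grid$n_lon * tau$j)
  n[as.integer(rownames(nm)) + 1L] <- as.integer(nm)
  if (!any(n > 0L))
    warning("no trajectory endpoint falls inside the grid; empty field")
  structure(list(grid = grid, n = n, tau = tau,
                 n_ave = if (any(n > 0L)) mean(n[n > 0L]) else NA_real_,
                 n_ave_all = mean(n),
                 outside = sum(!inside),
                 n_endpoints = nrow(set),
                 n_traj = max(traj_id), tau_mode = tau_mode),
            class = "residence_field")
}

#' @export
print.residence_field <- function(x, ...) {
  cat(sprintf(paste0("<residence_field> %d x %d grid, %d trajectories, ",
                     "%d endpoints (%d outside), n_ave = %.2f\n"),
              x$grid$n_lon, x$grid$n_lat, x$n_traj, x$n_endpoints,
              x$outside, x$n_ave))
  invisible(x)
}

#' Sparse-cell weighting function
#'
#' The standard piecewise-constant factor that downweights CWT values in
#' cells crossed by few trajectories, relative to the mean cell count
#' `n_ave`:
#' \deqn{W = 1.00 \ (n > 3 n_{ave});\ 0.70 \ (1.5 n_{ave} < n \le 3
#'   n_{ave});\ 0.42 \ (n_{ave} < n \le 1.5 n_{ave});\ 0.05 \ (n \le
#'   n_{ave}).}
#' Lower bounds are strict, upper bounds inclusive.
#'
#' @param n_ij Cell count(s), >= 0.
#' @param n_ave Mean cell count, > 0.
#' @return Numeric vector of weights in `{1, 0.70, 0.42, 0.05}`.
#' @examples
#' weight_factor(c(4, 3, 1.2, 1), n_ave = 1)  # 1.00 0.70 0.42 0.05
#' @export
weight_factor <- function(n_ij, n_ave) {
  if (!is.numeric(n_ave) || length(n_ave) != 1L || !is.finite(n_ave) ||
      n_ave <= 0)
    stop("`n_ave` must be a single positive number", call. = FALSE)
  if (any(n_ij < 0)) stop("cell counts must be >= 0", call. = FALSE)
  ifelse(n_ij > 3 * n_ave, 1.00,
         ifelse(n_ij > 1.5 * n_ave, 0.70,
                ifelse(n_ij > n_ave, 0.42, 0.05)))
}

#' Fit a concentration-weighted trajectory (CWT) field
#'
#' The CWT receptor model assigns each grid cell the residence-weighted
#' mean of the receptor concentrations measured when trajectories crossed
#' it:
#' \deqn{C_{ij} = \frac{\sum_l C_l \tau_{ijl}}{\sum_l \tau_{ijl}}
#'   \, W(n_{ij})}
#' where `C_l` is the receptor concentration at trajectory `l`'s arrival
#' time, `tau_ijl` its endpoint count in cell `(i,j)` and `W` the
#' sparse-cell weight of [weight_factor()]. Cells never crossed are
#' undefined (`NA`), not zero. By default `n_ave` is the mean count over
#' occupied cells; `nave_mode = "all"` averages over every cell of the
#' domain instead.
#'
#' @param trajectories A [traj_set()].
#' @param concentrations Data frame with `time` (POSIXct) and `pm25`; every
#'   arrival time must have a matching concentration.
#' @param grid A [make_grid()] spec (default [default_grid()]).
#' @param weighted Apply the sparse-cell weight (default `TRUE`).
#' @param nave_mode `"occupied"` (default) or `"all"`.
#' @param tau_mode `"endpoint"` (default) or `"indicator"`, see
#'   [residence_counts()].
#' @return An object of class `cwt`: list with `grid`, `conc` (the field,
#'   n_lon x n_lat, `NA` where undefined), `raw` (unweighted field), `n`,
#'   `W`, `n_ave`, `M` (number of trajectories), `arrivals`, `endpoints`
#'   (per-endpoint data frame with cell offsets), `outside`, plus the modes
#'   in effect. Methods: `print`, `summary`, `coef`, `predict`, `plot`.
#' @examples
#' cfg <- scenario_config(n_days = 2, seed = 42)
#' sc <- simulate_scenario(cfg)
#' fit <- cwt(sc$trajectories, sc$concentrations)
#' fit
#' @export
cwt <- function(trajectories, concentrations, grid = default_grid(),
                weighted = TRUE, nave_mode = c("occupied", "all"),
                tau_mode = c("endpoint", "indicator")) {
  stopifnot(inherits(trajectories, "traj_set"))
  nave_mode <- match.arg(nave_mode)
  tau_mode <- match.arg(tau_mode)
  if (!is.data.frame(concentrations) ||
      !all(c("time", "pm25") %in% names(concentrations)))
    stop("`concentrations` must have columns `time` and `pm25`",
         call. = FALSE)
  arr <- traj_arrivals(trajectories)
  cidx <- match(as.numeric(arr), as.numeric(concentrations$time))
  if (anyNA(cidx))
    stop("no concentration for arrival time(s): ",
         paste(format(arr[is.na(cidx)][seq_len(min(5, sum(is.na(cidx))))],
                      "%Y-%m-%d %H:%M", tz = "UTC"), collapse = ", "),
         call. = FALSE)
  c_arr <- concentrations$pm25[cidx]

  res <- residence_counts(trajectories, grid, tau_mode = tau_mode)
  ij <- cell_index(grid, trajectories$lon, trajectories$lat)
  ep <- data.frame(arrival_time = trajectories$arrival_time,
                   member = trajectories$member,
                   age_h = trajectories$age_h,
                   lon = trajectories$lon, lat = trajectories$lat,
                   i = ij[, 1L], j = ij[, 2L])
  ncell <- grid$n_lon * grid$n_lat
  ## Eq: numerator / denominator over tau, using the per-trajectory counts
  ## so that both endpoint and indicator counting share one code path.
  c_traj_all <- c_arr[match(trajectories$arrival_time, arr)]
  traj <- paste(as.numeric(trajectories$arrival_time), trajectories$member)
  c_of_traj <- c_traj_all[!duplicated(traj)]
  cell0 <- res$tau$i + grid$n_lon * res$tau$j
  num <- rowsum(res$tau$count * c_of_traj[res$tau$traj], cell0)
  den <- rowsum(res$tau$count, cell0)
  raw <- matrix(NA_real_, grid$n_lon, grid$n_lat)
  raw[as.integer(rownames(num)) + 1L] <- num / den
  n_ave <- if (nave_mode == "occupied") res$n_ave else res$n_ave_all
  W <- matrix(NA_real_, grid$n_lon, grid$n_lat)
  if (is.finite(n_ave) && n_ave > 0)
    W[res$n > 0L] <- weight_factor(res$n[res$n > 0L], n_ave)
  conc <- if (weighted) raw * W else raw
  if (!any(is.finite(conc)))
    warning("CWT field is undefined everywhere")
  structure(list(grid = grid, conc = conc, raw = raw, n = res$n, W = W,
                 n_ave = n_ave, nave_mode = nave_mode, tau_mode = tau_mode,
                 weighted = weighted, M = res$n_traj, arrivals = arr,
                 conc_at_arrival = c_arr, endpoints = ep,
                 outside = res$outside,
                 receptor = attr(trajectories, "receptor"),
                 call = match.call()),
            class = "cwt")
}

#' @export
print.cwt <- function(x, digits = 3, ...) {
  cat("Concentration-weighted trajectory field\n")
  cat(sprintf("  %d trajectories over %d arrival times; grid %d x %d (%g deg)\n",
              x$M, length(x$arrivals), x$grid$n_lon, x$grid$n_lat,
              x$grid$cell_size))
  cat(sprintf("  occupied cells: %d of %d; n_ave (%s) = %.2f; weighting %s\n",
              sum(x$n > 0L), length(x$n), x$nave_mode, x$n_ave,
              if (x$weighted) "on" else "off"))
  rng <- range(x$conc, na.rm = TRUE)
  cat(sprintf("  field range: %.*f .. %.*f ug/m3; %d endpoints outside domain\n",
              digits, rng[1L], digits, rng[2L], x$outside))
  invisible(x)
}

#' @export
summary.cwt <- function(object, sectors = default_sectors(), ...) {
  defined <- which(is.finite(object$conc), arr.ind = TRUE)
  ctr <- grid_centers(object$grid)
  top <- defined[order(object$conc[defined], decreasing = TRUE), ,
                 drop = FALSE]
  top <- utils::head(top, 5L)
  out <- list(
    field = summary(as.vector(object$conc[is.finite(object$conc)])),
    n_ave = object$n_ave, M = object$M,
    occupied = sum(object$n > 0L), cells = length(object$n),
    top_cells = data.frame(lon = ctr$lon[top[, 1L]], lat = ctr$lat[top[, 2L]],
                           n = object$n[top], C = object$conc[top]),
    sectors = tryCatch(sector_integrals(object, sectors),
                       error = function(e) NULL))
  class(out) <- "summary.cwt"
  out
}

#' @export
print.summary.cwt <- function(x, ...) {
  cat("CWT field summary\n")
  cat(sprintf("  %d trajectories; %d/%d cells occupied; n_ave = %.2f\n",
              x$M, x$occupied, x$cells, x$n_ave))
  cat("  defined-cell concentrations (ug/m3):\n")
  print(x$field)
  cat("  strongest cells:\n")
  print(x$top_cells, row.names = FALSE, digits = 4)
  if (!is.null(x$sectors)) {
    cat("  sector shares of the integrated field:\n")
    print(x$sectors[c("sector", "n_defined", "integral", "share")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.cwt <- function(object, ...) {
  ctr <- grid_centers(object$grid)
  out <- object$conc
  dimnames(out) <- list(lon = format(ctr$lon), lat = format(ctr$lat))
  out
}

#' Evaluate a CWT field at arbitrary locations
#'
#' @param object A fitted [cwt()] field.
#' @param newdata Data frame with `lon` and `lat` columns; defaults to the
#'   endpoints the field was fitted on.
#' @param ... Unused.
#' @return Numeric vector of field values; `NA` outside the domain or where
#'   the field is undefined.
#' @export
predict.cwt <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$endpoints
  stopifnot(all(c("lon", "lat") %in% names(newdata)))
  ij <- cell_index(object$grid, newdata$lon, newdata$lat)
  out <- rep(NA_real_, nrow(ij))
  ok <- !is.na(ij[, 1L])
  out[ok] <- object$conc[cbind(ij[ok, 1L] + 1L, ij[ok, 2L] + 1L)]
  out
}

#' Plot a CWT field
#'
#' Images the field on its grid, marks the receptor, and (optionally)
#' overlays source-sector boundaries.
#'
#' @param x A [cwt()] fit.
#' @param sectors Sector table to overlay, or `NULL`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.cwt <- function(x, sectors = default_sectors(), ...) {
  ctr <- grid_centers(x$grid)
  image(ctr$lon, ctr$lat, x$conc, col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "longitude (deg E)", ylab = "latitude (deg N)",
        main = "CWT field (ug/m3)", ...)
  if (!is.null(sectors))
    rect(sectors$lon_min, sectors$lat_min, sectors$lon_max, sectors$lat_max,
         border = "grey30", lty = 2)
  points(x$receptor[["lon"]], x$receptor[["lat"]], pch = 17, cex = 1.2)
  box()
  invisible(x)
}

#' Per-arrival-time endpoint slices of a fitted field
#'
#' The hourly-resolution view of the receptor model: the period-wide CWT
#' field stays fixed while each arrival time exposes its own ensemble
#' endpoints, ready for per-time sector attribution (see
#' [timewise_fractions()]).
#'
#' @param fit A [cwt()] fit.
#' @return Named list (one element per arrival time, in order) of endpoint
#'   data frames.
#' @export
cwt_slices <- function(fit) {
  stopifnot(inherits(fit, "cwt"))
  f <- factor(as.numeric(fit$endpoints$arrival_time),
              levels = as.numeric(fit$arrivals))
  out <- split(fit$endpoints, f)
  names(out) <- format(fit$arrivals, "%Y-%m-%d %H:%M", tz = "UTC")
  out
}

#' Export a CWT field as a cell table
#'
#' One row per grid cell: zero-based offsets, centre coordinates, count,
#' weight and field value.
#'
#' @param fit A [cwt()] fit.
#' @param path Optional CSV path; if `NULL` the data frame is returned only.
#' @return Data frame `i, j, lon_center, lat_center, n, W, C` (invisibly if
#'   written).
#' @export
cwt_export <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "cwt"))
  g <- fit$grid
  ctr <- grid_centers(g)
  idx <- expand.grid(i = seq_len(g$n_lon) - 1L, j = seq_len(g$n_lat) - 1L)
  out <- data.frame(idx,
                    lon_center = ctr$lon[idx$i + 1L],
                    lat_center = ctr$lat[idx$j + 1L],
                    n = as.vector(fit$n), W = as.vector(fit$W),
                    C = as.vector(fit$conc))
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
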