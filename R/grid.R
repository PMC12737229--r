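#' Define a regular longitude-latitude analysis grid
#'
#' Builds the cell geometry on which trajectory residence and the
#' concentration-weighted trajectory (CWT) field are computed. Cells are
#' half-open: cell `(i, j)` (zero-based offsets) covers
#' `[lon_min + i*s, lon_min + (i+1)*s) x [lat_min + j*s, lat_min + (j+1)*s)`
#' where `s` is `cell_size`. Points on the upper or right domain edge fall
#' outside the grid.
#'
#' If an extent is not an integer multiple of `cell_size` the domain is
#' expanded outward to the next full cell and a message is emitted.
#'
#' @param lon_min,lat_min Lower-left corner, decimal degrees.
#' @param lon_max,lat_max Upper-right corner, decimal degrees.
#' @param cell_size Cell edge in degrees (default 0.25, the resolution at
#'   which receptor-model residence gridding is usually done).
#' @return An object of class `cwt_grid`: a list with `lon_min`, `lat_min`,
#'   `cell_size`, `n_lon`, `n_lat`.
#' @examples
#' make_grid(108, 34, 120, 43, 0.25)   # 48 x 36 cells
#' @seealso [default_grid()], [cell_index()]
#' @export
make_grid <- function(lon_min, lat_min, lon_max, lat_max, cell_size = 0.25) {
  for (v in list(lon_min, lat_min, lon_max, lat_max))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("grid corners must be finite numbers", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L ||
      !is.finite(cell_size) || cell_size <= 0)
    stop("`cell_size` must be a positive number", call. = FALSE)
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("grid maxima must exceed minima on both axes", call. = FALSE)
  n_of <- function(lo, hi, what) {
    n <- (hi - lo) / cell_size
    if (abs(n - round(n)) > 1e-9) {
      n <- ceiling(n - 1e-9)
      message("expanding ", what, " extent to ", n, " full cells")
    } else n <- round(n)
    as.integer(n)
  }
  structure(list(lon_min = lon_min, lat_min = lat_min, cell_size = cell_size,
                 n_lon = n_of(lon_min, lon_max, "longitude"),
                 n_lat = n_of(lat_min, lat_max, "latitude")),
            class = "cwt_grid")
}

#' Default analysis domain
#'
#' The hull of the five default source sectors, `[108, 120] x [34, 43]`
#' degrees, at 0.25-degree resolution (48 x 36 cells).
#'
#' @return A `cwt_grid`.
#' @export
default_grid <- function() make_grid(108, 34, 120, 43, 0.25)

#' @export
print.cwt_grid <- function(x, ...) {
  cat(sprintf("<cwt_grid> %d x %d cells of %g deg, [%g, %g] x [%g, %g]\n",
              x$n_lon, x$n_lat, x$cell_size,
              x$lon_min, x$lon_min + x$n_lon * x$cell_size,
              x$lat_min, x$lat_min + x$n_lat * x$cell_size))
  invisible(x)
}

#' Locate points on a grid
#'
#' Maps coordinates to zero-based cell offsets `(i, j)` under the half-open
#' cell convention: `i = floor((lon - lon_min)/s)`, `j = floor((lat -
#' lat_min)/s)`. Points outside the domain (including the upper/right edge)
#' get `NA`.
#'
#' @param grid A `cwt_grid`.
#' @param lon,lat Coordinate vectors (degrees), recycled to common length.
#' @return Integer matrix with columns `i`, `j`; `NA` rows mark points
#'   outside the grid.
#' @examples
#' g <- make_grid(108, 34, 120, 43)
#' cell_index(g, 116.40, 39.98)  # i = 33, j = 23
#' @export
cell_index <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "cwt_grid"))
  n <- max(length(lon), length(lat))
  lon <- rep_len(as.numeric(lon), n)
  lat <- rep_len(as.numeric(lat), n)
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("coordinates must be finite", call. = FALSE)
  i <- floor((lon - grid$lon_min) / grid$cell_size)
  j <- floor((lat - grid$lat_min) / grid$cell_size)
  out <- i < 0 | i >= grid$n_lon | j < 0 | j >= grid$n_lat
  i[out] <- NA_integer_; j[out] <- NA_integer_
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A `cwt_grid`.
#' @return List with vectors `lon` (length `n_lon`) and `lat` (length
#'   `n_lat`) of cell-centre coordinates.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "cwt_grid"))
  list(lon = grid$lon_min + (seq_len(grid$n_lon) - 0.5) * grid$cell_size,
       lat = grid$lat_min + (seq_len(grid$n_lat) - 0.5) * grid$cell_size)
}
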