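#' Default source sectors around the Beijing receptor
#'
#' Five rectangular source regions that tile the analysis domain
#' `[108, 120) x [34, 43)` degrees: the central Beijing ("local") region
#' (115.3-117.5 E, 39.4-41 N), the western plateau (108-115.3 E, 34-41 N),
#' the northern plateau (108-117.5 E, 41-43 N), the eastern coastal plain
#' (117.5-120 E, 39.4-43 N) and the southern region (115.3-120 E,
#' 34-39.4 N). Shared edges follow the half-open convention (lower/left
#' closed), so the rectangles are pairwise disjoint and cover the domain
#' exactly.
#'
#' @return A `cwt_sectors` data frame with columns `name`, `lon_min`,
#'   `lon_max`, `lat_min`, `lat_max`.
#' @export
default_sectors <- function() {
  structure(data.frame(
    name = c("local", "west", "north", "east", "south"),
    lon_min = c(115.3, 108, 108, 117.5, 115.3),
    lon_max = c(117.5, 115.3, 117.5, 120, 120),
    lat_min = c(39.4, 34, 41, 39.4, 34),
    lat_max = c(41, 41, 43, 43, 39.4),
    stringsAsFactors = FALSE),
    class = c("cwt_sectors", "data.frame"))
}

#' Validate a sector table
#' @param sectors Data frame with `name`, `lon_min`, `lon_max`, `lat_min`,
#'   `lat_max`.
#' @return The table, classed `cwt_sectors`.
#' @export
as_sectors <- function(sectors) {
  need <- c("name", "lon_min", "lon_max", "lat_min", "lat_max")
  if (!is.data.frame(sectors) || !all(need %in% names(sectors)))
    stop("sectors need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(sectors$lon_min >= sectors$lon_max) ||
      any(sectors$lat_min >= sectors$lat_max))
    stop("sector minima must be below maxima", call. = FALSE)
  if (anyDuplicated(sectors$name))
    stop("duplicate sector names", call. = FALSE)
  structure(sectors, class = c("cwt_sectors", "data.frame"))
}

#' Classify points into source sectors
#'
#' Membership is half-open (`lon_min <= lon < lon_max`, same for latitude),
#' so on a tiling sector set every point matches at most one sector.
#'
#' @param sectors A sector table, see [default_sectors()].
#' @param lon,lat Coordinate vectors (degrees), recycled.
#' @return Character vector of sector names, `"outside"` where no sector
#'   matches.
#' @examples
#' classify_point(default_sectors(), c(116.0, 121.0), c(40.0, 40.0))
#' @export
classify_point <- function(sectors, lon, lat) {
  sectors <- as_sectors(sectors)
  n <- max(length(lon), length(lat))
  lon <- rep_len(as.numeric(lon), n); lat <- rep_len(as.numeric(lat), n)
  out <- rep("outside", n)
  for (k in seq_len(nrow(sectors))) {
    hit <- lon >= sectors$lon_min[k] & lon < sectors$lon_max[k] &
      lat >= sectors$lat_min[k] & lat < sectors$lat_max[k]
    out[hit] <- sectors$name[k]
  }
  out
}

sector_of_cells <- function(grid, sectors) {
  ## a grid cell belongs to the sector containing its centre, which keeps
  ## cells straddling sector edges (e.g. at 115.3 E on a 0.25-deg grid)
  ## unambiguous
  ctr <- grid_centers(grid)
  cells <- expand.grid(lon = ctr$lon, lat = ctr$lat)
  matrix(classify_point(sectors, cells$lon, cells$lat),
         grid$n_lon, grid$n_lat)
}

#' Integrate a CWT field over source sectors
#'
#' Sums the defined field values over the cells of each sector (cells
#' belong to the sector containing their centre) and normalises to shares.
#' Cells outside every sector are reported in the `"outside"` attribute.
#'
#' @param fit A [cwt()] fit, or any list with `grid` and `conc`.
#' @param sectors Sector table (default [default_sectors()]).
#' @return Data frame `sector, n_cells, n_defined, integral, share`, with
#'   attribute `outside` (list `n_defined`, `integral`).
#' @export
sector_integrals <- function(fit, sectors = default_sectors()) {
  stopifnot(!is.null(fit$grid), !is.null(fit$conc))
  sectors <- as_sectors(sectors)
  if (!any(is.finite(fit$conc)))
    stop("CWT field has no defined cells", call. = FALSE)
  sec <- sector_of_cells(fit$grid, sectors)
  defined <- is.finite(fit$conc)
  int <- vapply(sectors$name, function(s)
    sum(fit$conc[defined & sec == s]), numeric(1))
  out <- data.frame(sector = sectors$name,
                    n_cells = vapply(sectors$name, function(s)
                      sum(sec == s), integer(1)),
                    n_defined = vapply(sectors$name, function(s)
                      sum(defined & sec == s), integer(1)),
                    integral = int,
                    share = if (sum(int) > 0) int / sum(int)
                            else rep(NA_real_, length(int)))
  attr(out, "outside") <- list(n_defined = sum(defined & sec == "outside"),
                               integral = sum(fit$conc[defined &
                                                         sec == "outside"]))
  rownames(out) <- NULL
  out
}

#' Per-arrival-time air-mass source fractions
#'
#' For each arrival time, distributes that ensemble's endpoints over the
#' source sectors and normalises. Two weighting modes:
#' * `"cwt"` (concentration-weighted origin): each endpoint carries the
#'   period-wide CWT value of its cell (0 where the field is undefined or
#'   the endpoint leaves the domain), so the fractions reflect where the
#'   *pollution* associated with that arrival resided;
#' * `"count"` (air-mass origin): every endpoint counts 1, so the fractions
#'   reflect where the *air* resided, regardless of pollution. This is the
#'   mode used for regime labelling.
#'
#' Ties for the dominant sector are broken by the fixed priority
#' local, south, east, west, north and flagged. A record whose total
#' endpoint weight is zero is flagged indeterminate.
#'
#' @param fit A [cwt()] fit.
#' @param sectors Sector table (default [default_sectors()]).
#' @param weighting `"cwt"` (default) or `"count"`.
#' @return A `cwt_attribution` data frame: `time`, one fraction column per
#'   sector, `outside`, `dominant`, `tie`, `indeterminate`.
#' @export
timewise_fractions <- function(fit, sectors = default_sectors(),
                               weighting = c("cwt", "count")) {
  stopifnot(inherits(fit, "cwt"))
  weighting <- match.arg(weighting)
  sectors <- as_sectors(sectors)
  ep <- fit$endpoints
  inside <- !is.na(ep$i)
  ## endpoint sector = sector of its cell's centre (consistent with
  ## sector_integrals); endpoints off the domain are "outside"
  sec <- rep("outside", nrow(ep))
  if (any(inside)) {
    ctr <- grid_centers(fit$grid)
    sec[inside] <- classify_point(sectors, ctr$lon[ep$i[inside] + 1L],
                                  ctr$lat[ep$j[inside] + 1L])
  }
  w <- if (weighting == "count") rep(1, nrow(ep)) else {
    v <- rep(0, nrow(ep))
    v[inside] <- fit$conc[cbind(ep$i[inside] + 1L, ep$j[inside] + 1L)]
    v[!is.finite(v)] <- 0
    v
  }
  grp <- match(as.numeric(ep$arrival_time), as.numeric(fit$arrivals))
  tot <- as.vector(rowsum(w, grp))
  cols <- c(sectors$name, "outside")
  fr <- vapply(cols, function(s)
    as.vector(rowsum(w * (sec == s), grp)), numeric(length(fit$arrivals)))
  fr <- matrix(fr, ncol = length(cols),
               dimnames = list(NULL, cols))
  indet <- tot <= 0
  fr[!indet, ] <- fr[!indet, , drop = FALSE] / tot[!indet]
  fr[indet, ] <- NA_real_
  prio <- intersect(.sector_priority, sectors$name)
  prio <- c(prio, setdiff(sectors$name, prio))
  fm <- fr[, prio, drop = FALSE]
  pick <- function(v) if (all(is.na(v))) NA_integer_ else which.max(v)
  best <- apply(fm, 1L, pick)
  tie <- vapply(seq_len(nrow(fm)), function(r) {
    v <- fm[r, ]
    !all(is.na(v)) && sum(abs(v - max(v)) < 1e-12) > 1L
  }, logical(1))
  out <- data.frame(time = fit$arrivals, fr,
                    dominant = prio[best], tie = tie,
                    indeterminate = indet, check.names = FALSE)
  structure(out, sectors = sectors$name, weighting = weighting,
            class = c("cwt_attribution", "data.frame"))
}

#' Label each day's dominant air-mass source
#'
#' A day's label is the sector with the largest mean fraction over the
#' day's attribution records (indeterminate records excluded). Ties follow
#' the same fixed priority as [timewise_fractions()] and are flagged. Days
#' with no usable record are skipped with a warning.
#'
#' @param records A `cwt_attribution` from [timewise_fractions()].
#' @param tz Reporting timezone for the calendar day (default UTC).
#' @return Data frame `date`, `source`, `tie`, `n_records`.
#' @export
dominant_source_per_day <- function(records, tz = "UTC") {
  stopifnot(inherits(records, "cwt_attribution"))
  secs <- attr(records, "sectors")
  day <- as.Date(records$time, tz = tz)
  ok <- !records$indeterminate
  if (!any(ok)) stop("no determinate attribution records", call. = FALSE)
  dropped <- setdiff(unique(day), unique(day[ok]))
  if (length(dropped))
    warning("skipping day(s) with no determinate records: ",
            paste(as.Date(dropped, origin = "1970-01-01"), collapse = ", "))
  m <- aggregate(records[ok, secs, drop = FALSE], list(date = day[ok]), mean)
  prio <- intersect(.sector_priority, secs)
  prio <- c(prio, setdiff(secs, prio))
  fm <- as.matrix(m[, prio, drop = FALSE])
  best <- apply(fm, 1L, which.max)
  tie <- vapply(seq_len(nrow(fm)), function(r)
    sum(abs(fm[r, ] - max(fm[r, ])) < 1e-12) > 1L, logical(1))
  data.frame(date = m$date, source = prio[best], tie = tie,
             n_records = as.vector(table(day[ok])[as.character(m$date)]))
}
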