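#' Trajectory endpoint sets
#'
#' The package represents backward-trajectory ensembles as a single
#' data frame of endpoints, one row per (arrival time, ensemble member,
#' age) triple, with the receptor location attached as an attribute.
#' An *ensemble* is the group of members sharing one arrival time; a
#' `traj_set` holds any number of ensembles.
#'
#' Columns: `arrival_time` (POSIXct, UTC), `member` (integer >= 1),
#' `age_h` (integer <= 0; 0 is the arrival point, -24 the oldest endpoint of
#' a 24-h back-trajectory), `lat`, `lon` (degrees; `lon` normalised to
#' \[-180, 180)), `height` (metres above ground).
#'
#' Validation enforces that within each member the ages are unique and form
#' a contiguous descending run `0, -1, ..., -K`, and that every member's
#' age-0 endpoint coincides with the receptor within `tol` degrees.
#'
#' @param points Data frame with the columns listed above.
#' @param receptor Named numeric `c(lat=, lon=)`; defaults to the Beijing
#'   urban monitoring site (39.98 N, 116.40 E).
#' @param tol Allowed mismatch (degrees) between age-0 endpoints and the
#'   receptor.
#' @param check Run validation (set `FALSE` only for trusted internal data).
#' @return A `traj_set`: the data frame with attributes `receptor` and class
#'   `c("traj_set", "data.frame")`.
#' @export
traj_set <- function(points, receptor = .receptor_default, tol = 0.01,
                     check = TRUE) {
  need <- c("arrival_time", "member", "age_h", "lat", "lon", "height")
  if (!is.data.frame(points) || !all(need %in% names(points)))
    stop("`points` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(points) == 0L) stop("trajectory set has no endpoints", call. = FALSE)
  points <- points[need]
  if (!inherits(points$arrival_time, "POSIXct"))
    stop("`arrival_time` must be POSIXct", call. = FALSE)
  attr(points$arrival_time, "tzone") <- "UTC"
  points$member <- as.integer(points$member)
  points$age_h <- as.integer(points$age_h)
  points$lon <- normalize_lon(points$lon)
  ord <- order(points$arrival_time, points$member, -points$age_h)
  points <- points[ord, , drop = FALSE]
  rownames(points) <- NULL
  if (check) validate_traj(points, receptor, tol)
  structure(points, receptor = receptor,
            class = c("traj_set", "data.frame"))
}

#' Normalise longitudes to \[-180, 180)
#' @param lon Numeric vector of longitudes in degrees (any wrap).
#' @return Numeric vector in \[-180, 180).
#' @export
normalize_lon <- function(lon) ((lon + 180) %% 360) - 180

validate_traj <- function(points, receptor, tol) {
  bad <- !is.finite(points$lat) | !is.finite(points$lon)
  if (any(bad))
    stop("non-finite coordinates at endpoint row(s) ",
         paste(utils::head(which(bad), 3L), collapse = ", "), call. = FALSE)
  if (any(points$lat < -90 | points$lat > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(points$member < 1L, na.rm = TRUE) || anyNA(points$member))
    stop("member ids must be integers >= 1", call. = FALSE)
  if (any(points$age_h > 0L, na.rm = TRUE) || anyNA(points$age_h))
    stop("ages must be integers <= 0", call. = FALSE)
  ## contiguity: rows are sorted by (arrival, member, -age); each group must
  ## run 0, -1, ..., -(k-1)
  key <- paste(as.numeric(points$arrival_time), points$member)
  r <- rle(key)
  expected <- -(sequence(r$lengths) - 1L)
  if (!identical(as.integer(points$age_h), as.integer(expected))) {
    off <- which(points$age_h != expected)[1L]
    stop(sprintf(paste0("member %d (arrival %s) has non-contiguous ages: ",
                        "expected %d, found %d"),
                 points$member[off],
                 format(points$arrival_time[off], "%Y-%m-%d %H:%M",
                        tz = "UTC"),
                 expected[off], points$age_h[off]), call. = FALSE)
  }
  a0 <- points[points$age_h == 0L, , drop = FALSE]
  dev <- pmax(abs(a0$lat - receptor[["lat"]]),
              abs(normalize_lon(a0$lon - receptor[["lon"]])))
  if (any(dev > tol)) {
    off <- which.max(dev)
    stop(sprintf("member %d arrival point (%.3f, %.3f) is %.3f deg from the receptor",
                 a0$member[off], a0$lat[off], a0$lon[off], dev[off]),
         call. = FALSE)
  }
  invisible(points)
}

#' @export
print.traj_set <- function(x, ...) {
  arr <- unique(x$arrival_time)
  cat(sprintf(paste0("<traj_set> %d endpoints, %d arrival time(s), ",
                     "%d member(s) per ensemble\n"),
              nrow(x), length(arr),
              length(unique(x$member[x$arrival_time == arr[1L]]))))
  cat(sprintf("  receptor %.2f N, %.2f E; arrivals %s .. %s UTC\n",
              attr(x, "receptor")[["lat"]], attr(x, "receptor")[["lon"]],
              format(min(arr), "%Y-%m-%d %H:%M"),
              format(max(arr), "%Y-%m-%d %H:%M")))
  invisible(x)
}

#' Arrival times of a trajectory set
#' @param set A `traj_set`.
#' @return Sorted POSIXct vector of distinct arrival times.
#' @export
traj_arrivals <- function(set) sort(unique(set$arrival_time))

## ---- HYSPLIT-style endpoint ("tdump") files ------------------------------

#' Read a HYSPLIT-style trajectory endpoint file
#'
#' Parses the multi-trajectory endpoint ("tdump") layout: a met-grid header,
#' a trajectory count line, one start line per trajectory, a diagnostics
#' line, then whitespace-delimited data records
#' `member grid yy mm dd hh mn fcst age lat lon height diag...`.
#' Only positions are used; diagnostic columns beyond height are ignored.
#' Ensembles are grouped by arrival time, computed per record as
#' `record time - age` (ages are negative for backward runs). Longitudes are
#' normalised to \[-180, 180). Timestamps are taken as UTC.
#'
#' @param path Path to an endpoint file.
#' @param receptor Receptor `c(lat=, lon=)`; if `NULL` it is taken from the
#'   first trajectory start line.
#' @param tol Receptor coincidence tolerance in degrees.
#' @return A [traj_set()].
#' @seealso [write_tdump()]
#' @export
read_tdump <- function(path, receptor = NULL, tol = 0.01) {
  if (!file.exists(path)) stop("endpoint file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("endpoint format error: file is empty", call. = FALSE)
  num_at <- function(line, lineno) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1L]]))
    if (anyNA(v))
      stop("endpoint format error at line ", lineno, ": non-numeric field",
           call. = FALSE)
    v
  }
  ngrid <- suppressWarnings(
    as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]][1L]))
  if (is.na(ngrid) || ngrid < 1L)
    stop("endpoint format error at line 1: bad met-grid count", call. = FALSE)
  pos <- 1L + ngrid                       # last met-grid header line
  if (length(lines) <= pos + 1L)
    stop("endpoint format error: truncated header", call. = FALSE)
  ntraj_line <- strsplit(trimws(lines[pos + 1L]), "\\s+")[[1L]]
  ntraj <- suppressWarnings(as.integer(ntraj_line[1L]))
  if (is.na(ntraj) || ntraj < 1L)
    stop("endpoint format error at line ", pos + 1L, ": bad trajectory count",
         call. = FALSE)
  start_lines <- lines[pos + 1L + seq_len(ntraj)]
  if (length(start_lines) < ntraj || anyNA(start_lines))
    stop("endpoint format error: missing trajectory start lines",
         call. = FALSE)
  if (is.null(receptor)) {
    s1 <- num_at(start_lines[1L], pos + 2L)
    receptor <- c(lat = s1[5L], lon = s1[6L])
  }
  data_from <- pos + 1L + ntraj + 2L      # after the diagnostics line
  if (length(lines) < data_from)
    stop("endpoint format error: no data records", call. = FALSE)
  rec_lines <- lines[data_from:length(lines)]
  toks <- strsplit(trimws(rec_lines), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 12L))
    stop("endpoint format error at line ",
         data_from - 1L + which(nf < 12L)[1L], ": record too short",
         call. = FALSE)
  m <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(toks, `[`, 1:12))), ncol = 12L,
           byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop("endpoint format error at line ", data_from - 1L + bad,
         ": non-numeric field", call. = FALSE)
  }
  yy <- m[, 3L]
  year <- ifelse(yy >= 100, yy, ifelse(yy > 69, 1900 + yy, 2000 + yy))
  when <- ISOdatetime(year, m[, 4L], m[, 5L], m[, 6L], m[, 7L], 0, tz = "UTC")
  age <- m[, 9L]
  if (any(abs(age - round(age)) > 1e-6))
    stop("endpoint format error: fractional trajectory age", call. = FALSE)
  age <- as.integer(round(age))
  pts <- data.frame(arrival_time = when - age * 3600,
                    member = as.integer(m[, 1L]),
                    age_h = age, lat = m[, 10L], lon = m[, 11L],
                    height = m[, 12L])
  traj_set(pts, receptor = receptor, tol = tol)
}

#' Write a trajectory set as a HYSPLIT-style endpoint file
#'
#' Emits the layout read by [read_tdump()]. Coordinates are written with
#' three decimals (the endpoint format's precision), heights and ages with
#' one; a read-back therefore reproduces the set exactly at that precision.
#'
#' @param set A non-empty [traj_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tdump <- function(set, path) {
  stopifnot(inherits(set, "traj_set"))
  if (nrow(set) == 0L) stop("cannot write an empty trajectory set",
                            call. = FALSE)
  set <- set[order(set$arrival_time, set$member, -set$age_h), , drop = FALSE]
  key <- paste(as.numeric(set$arrival_time), set$member)
  starts <- set[!duplicated(key), , drop = FALSE]   # age-0 rows
  ntraj <- nrow(starts)
  t0 <- starts$arrival_time[1L]
  yy <- function(t) as.integer(format(t, "%y", tz = "UTC"))
  fld <- function(t, f) as.integer(format(t, f, tz = "UTC"))
  out <- c(
    sprintf("%6d%6d", 1L, 1L),
    sprintf("%8s%6d%6d%6d%6d%6d", "SYNT", yy(t0), fld(t0, "%m"),
            fld(t0, "%d"), fld(t0, "%H"), 0L),
    sprintf("%6d %-8s %-8s", ntraj, "BACKWARD", "OMEGA"),
    sprintf("%6d%6d%6d%6d %9.3f %9.3f %9.1f",
            yy(starts$arrival_time), fld(starts$arrival_time, "%m"),
            fld(starts$arrival_time, "%d"), fld(starts$arrival_time, "%H"),
            starts$lat, starts$lon, starts$height),
    sprintf("%6d %-8s", 1L, "PRESSURE"))
  when <- set$arrival_time + set$age_h * 3600
  rec <- sprintf("%6d%6d%6d%6d%6d%6d%6d%6d%8.1f%9.3f%9.3f%9.1f%9.1f",
                 set$member, 1L, yy(when), fld(when, "%m"), fld(when, "%d"),
                 fld(when, "%H"), fld(when, "%M"), 0L, as.numeric(set$age_h),
                 set$lat, set$lon, set$height, 0)
  tryCatch(writeLines(c(out, rec), path),
           error = function(e) stop("cannot write endpoint file '", path,
                                    "': ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read an hourly concentration (and optional meteorology) series
#'
#' Expects a CSV with a `time` column (ISO 8601, interpreted as UTC) and a
#' `pm25` column in micrograms per cubic metre; optional columns `ws`
#' (m/s), `rh` (percent), `t` (degrees C), `p` (hPa) are carried through.
#'
#' @param path CSV path.
#' @return Data frame with POSIXct `time` plus the value columns.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "pm25") %in% names(d)))
    stop("series must have columns `time` and `pm25`", call. = FALSE)
  d$time <- as.POSIXct(d$time, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                      "%Y-%m-%d %H:%M:%OS",
                                      "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (anyNA(d$time)) stop("unparseable timestamps in series", call. = FALSE)
  d
}

#' Write a concentration/meteorology series as CSV
#' @param series Data frame with POSIXct `time` and value columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  series$time <- format(series$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}
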