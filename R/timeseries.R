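#' Hourly monitoring series
#'
#' Container for one station/pollutant hourly concentration record.  Values
#' are indexed by consecutive calendar hours starting at `start`; gaps in the
#' record are explicit `NA` entries, never skipped hours.
#'
#' @param station Station identifier (coerced to character).
#' @param pollutant Pollutant or index name.
#' @param start `POSIXct` timestamp of the first hour.
#' @param values Numeric vector of non-negative concentrations, `NA` for
#'   missing hours.
#' @return An object of class `hourly_series`.
#' @export
hourly_series <- function(station, pollutant, start, values) {
  if (!inherits(start, "POSIXct")) {
    start <- as.POSIXct(start, tz = "UTC")
  }
  if (is.na(start)) {
    stop_riacd("'start' is not a parseable timestamp", "riacd_format_error")
  }
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) {
    stop_riacd("concentration values must be non-negative", "riacd_validation_error")
  }
  structure(
    list(station = as.character(station), pollutant = as.character(pollutant),
         start = start, values = values),
    class = "hourly_series"
  )
}

#' @export
print.hourly_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<%s> station %s, %s: %d hours from %s (%d missing)\n",
              class(x)[1L], x$station, x$pollutant, n,
              format(x$start, "%Y-%m-%d %H:%M"), sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.hourly_series <- function(x) length(x$values)

parse_hour_stamp <- function(ts, tz = "UTC") {
  ts <- as.character(ts)
  out <- as.POSIXct(ts, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  alt <- is.na(out)
  if (any(alt)) {
    out[alt] <- as.POSIXct(ts[alt], tz = tz, format = "%Y-%m-%d %H:%M:%S")
  }
  alt <- is.na(out)
  if (any(alt)) {
    out[alt] <- as.POSIXct(ts[alt], tz = tz, format = "%Y-%m-%dT%H:%M")
  }
  alt <- is.na(out)
  if (any(alt)) {
    out[alt] <- as.POSIXct(ts[alt], tz = tz, format = "%Y-%m-%d %H:%M")
  }
  out
}

#' Read hourly station data from CSV
#'
#' Expects one row per (station, pollutant, hour).  Hours absent from the
#' file inside each series' span become explicit missing entries, so the
#' returned series have no calendar gaps.
#'
#' @param path CSV file with columns mapped by `schema`.
#' @param schema Named character vector mapping the roles `station`,
#'   `pollutant`, `timestamp`, `value` to column names in the file.
#' @param tz Time zone used to interpret timestamps (no conversion is done;
#'   hours-of-day are taken from the stamps as written).
#' @return Named list of [hourly_series], one per (station, pollutant), names
#'   `"station.pollutant"`.
#' @export
read_hourly_csv <- function(path,
                            schema = c(station = "station",
                                       pollutant = "pollutant",
                                       timestamp = "timestamp",
                                       value = "value"),
                            tz = "UTC") {
  if (!file.exists(path)) {
    stop_riacd(sprintf("file not found: %s", path), "riacd_format_error")
  }
  if (file.size(path) == 0L) return(list())
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- schema[c("station", "pollutant", "timestamp", "value")]
  if (!all(need %in% names(df))) {
    stop_riacd(sprintf("missing columns: %s",
                       paste(setdiff(need, names(df)), collapse = ", ")),
               "riacd_format_error")
  }
  if (nrow(df) == 0L) return(list())
  stamp <- parse_hour_stamp(df[[need[["timestamp"]]]], tz = tz)
  if (anyNA(stamp)) {
    stop_riacd("unparseable timestamp(s) in input", "riacd_format_error")
  }
  val <- df[[need[["value"]]]]
  if (is.character(val)) val[val %in% c("", "NA")] <- NA
  val <- as.numeric(val)
  if (any(val < 0, na.rm = TRUE)) {
    stop_riacd("negative concentration value(s) in input", "riacd_validation_error")
  }
  key <- paste(df[[need[["station"]]]], df[[need[["pollutant"]]]], sep = ".")
  if (anyDuplicated(paste(key, format(stamp, "%Y-%m-%d %H", tz = tz)))) {
    stop_riacd("duplicate (station, pollutant, hour) rows", "riacd_integrity_error")
  }
  out <- lapply(split(seq_along(key), key), function(ix) {
    st <- stamp[ix]
    o <- order(st)
    ix <- ix[o]; st <- st[o]
    grid <- seq(st[1L], st[length(st)], by = "hour")
    v <- rep(NA_real_, length(grid))
    v[match(as.numeric(st), as.numeric(grid))] <- val[ix]
    hourly_series(df[[need[["station"]]]][ix[1L]],
                  df[[need[["pollutant"]]]][ix[1L]], grid[1L], v)
  })
  out[order(names(out))]
}

#' Write hourly series to CSV
#'
#' Inverse of [read_hourly_csv()]: missing hours are written as empty value
#' fields so a read/write/read round trip preserves values and missing masks.
#'
#' @param series A single [hourly_series] or a list of them.
#' @param path Output CSV path.
#' @export
write_hourly_csv <- function(series, path) {
  if (inherits(series, "hourly_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(
      station = s$station, pollutant = s$pollutant,
      timestamp = format(seq(s$start, by = "hour", length.out = length(s$values)),
                         "%Y-%m-%dT%H:%M:%S"),
      value = s$values, stringsAsFactors = FALSE
    )
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

hour_of_day <- function(x) {
  h0 <- as.integer(format(x$start, "%H"))
  (h0 + seq_along(x$values) - 1L) %% 24L
}

#' Remove the diurnal cycle from an hourly series
#'
#' Each value is divided by the across-day average concentration at the same
#' hour of day, computed over present values only.  The adjusted series is
#' dimensionless with per-hour-of-day day means exactly 1 and overall mean
#' close to 1; missing hours stay missing.
#'
#' @param x An [hourly_series].
#' @return An `adjusted_series` (same shape, dimensionless values).
#' @export
diurnal_adjust <- function(x) {
  stopifnot(inherits(x, "hourly_series"))
  hod <- hour_of_day(x)
  means <- vapply(0:23, function(h) {
    v <- x$values[hod == h]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  used <- !is.na(means)
  if (any(means[used] == 0)) {
    stop_riacd("hour-of-day with zero across-day average; cannot adjust",
               "riacd_degenerate_hour_error")
  }
  out <- x
  out$values <- x$values / means[hod + 1L]
  class(out) <- c("adjusted_series", "hourly_series")
  out
}

#' Station registry
#'
#' @param df Data frame with columns `label` (unique small integers), `code`,
#'   `longitude` (degrees east), `latitude` (degrees north).
#' @return A `station_registry` data frame.
#' @export
station_registry <- function(df) {
  need <- c("label", "code", "longitude", "latitude")
  if (!all(need %in% names(df))) {
    stop_riacd("registry needs columns label, code, longitude, latitude",
               "riacd_format_error")
  }
  df <- df[need]
  if (anyDuplicated(df$label)) {
    stop_riacd("duplicate station labels", "riacd_integrity_error")
  }
  if (any(df$latitude < -90 | df$latitude > 90) ||
      any(df$longitude < -180 | df$longitude > 180)) {
    stop_riacd("coordinates out of range", "riacd_validation_error")
  }
  df <- df[order(df$label), ]
  rownames(df) <- NULL
  class(df) <- c("station_registry", "data.frame")
  df
}

#' @rdname station_registry
#' @param path CSV file in registry layout.
#' @export
read_station_registry <- function(path) {
  station_registry(read.csv(path, stringsAsFactors = FALSE))
}

#' Beijing national monitoring station registry
#'
#' The 12 national air-quality monitoring stations in Beijing (label, code and
#' two-decimal coordinates) shipped as a package fixture.
#'
#' @return A `station_registry` with 12 rows.
#' @export
beijing_stations <- function() {
  read_station_registry(system.file("extdata", "beijing_stations.csv",
                                    package = "riacd", mustWork = TRUE))
}

#' Pairwise great-circle distances between stations
#'
#' Haversine distances on a sphere of radius 6371 km, together with each
#' station's neighbour ordering (ascending distance, ties broken by ascending
#' label).
#'
#' @param reg A [station_registry] with at least two stations.
#' @return A `distance_matrix` object: list with `distances` (km, labelled
#'   square matrix) and `neighbours` (named list of label vectors, nearest
#'   first).
#' @export
interstation_distances <- function(reg) {
  reg <- station_registry(as.data.frame(reg))
  n <- nrow(reg)
  if (n < 2L) stop_riacd("need at least two stations", "riacd_validation_error")
  p <- cbind(reg$longitude, reg$latitude)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  d <- geosphere::distHaversine(p[ij$i, , drop = FALSE],
                                p[ij$j, , drop = FALSE], r = 6371000) / 1000
  d <- matrix(d, n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  lab <- as.character(reg$label)
  dimnames(d) <- list(lab, lab)
  nb <- lapply(seq_len(n), function(i) {
    o <- setdiff(seq_len(n), i)
    reg$label[o[order(d[i, o], reg$label[o])]]
  })
  names(nb) <- lab
  structure(list(distances = d, neighbours = nb, labels = reg$label),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d stations, %.1f-%.1f km\n",
              length(x$labels), min(x$distances[upper.tri(x$distances)]),
              max(x$distances)))
  invisible(x)
}
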