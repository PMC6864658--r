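#' Truncate timestamps to the containing hour
#'
#' Hours are labelled by their start and are half-open intervals
#' \code{[t, t + 1h)}.
#'
#' @param time a POSIXct vector.
#' @return POSIXct vector truncated to the hour, keeping the time zone.
#' @export
trunc_hour <- function(time) {
  stopifnot(inherits(time, "POSIXct"))
  tz <- attr(time, "tzone")
  if (is.null(tz)) tz <- ""
  as.POSIXct(floor(as.numeric(time) / 3600) * 3600,
             origin = "1970-01-01", tz = tz)
}

#' Aggregate minute-level sensor records to hourly means
#'
#' One-minute PM2.5 values are averaged to hourly values, requiring 75%
#' completeness for each hour: an hourly mean is reported only when at least
#' \code{min_minutes} (default 45 of 60) valid minute values fall in the hour.
#' The count of contributing minutes is always reported. Negative PM2.5
#' values are invalid and are dropped (not clipped); the number dropped is
#' attached as attribute \code{"qc"}.
#'
#' @param records data.frame with columns \code{sensor_id}, \code{timestamp}
#'   (POSIXct, minute resolution) and \code{pm25} (ug/m3).
#' @param min_minutes minimum number of valid minutes for a valid hour.
#' @return data.frame with columns \code{sensor_id}, \code{hour_start},
#'   \code{pm25} (NA when the hour is incomplete) and \code{n_minutes}.
#' @export
aggregate_to_hours <- function(records, min_minutes = 45) {
  stopifnot(is.data.frame(records),
            all(c("sensor_id", "timestamp", "pm25") %in% names(records)))
  neg <- !is.na(records$pm25) & records$pm25 < 0
  n_neg <- sum(neg)
  if (n_neg > 0) records$pm25[neg] <- NA_real_

  hour <- trunc_hour(records$timestamp)
  key <- paste(records$sensor_id, as.numeric(hour))
  ok <- !is.na(records$pm25)
  sums <- rowsum(ifelse(ok, records$pm25, 0), key)
  cnts <- rowsum(as.numeric(ok), key)

  first <- !duplicated(key)
  map <- data.frame(key = key[first],
                    sensor_id = records$sensor_id[first],
                    hour_start = hour[first],
                    stringsAsFactors = FALSE)
  map <- map[match(rownames(sums), map$key), ]

  n_minutes <- as.integer(cnts[, 1])
  pm25 <- ifelse(n_minutes >= min_minutes, sums[, 1] / n_minutes, NA_real_)
  out <- data.frame(sensor_id = map$sensor_id,
                    hour_start = map$hour_start,
                    pm25 = pm25,
                    n_minutes = n_minutes,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sensor_id, out$hour_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- list(n_dropped_negative = n_neg)
  out
}

#' Aggregate hourly records to daily means
#'
#' Daily means are computed over valid hours only, with the same 75%
#' completeness convention used for hours: a daily value is reported when at
#' least \code{min_hours} (default 18 of 24) hourly values are valid. Day
#' boundaries follow \code{tz}, the local standard time of the study region.
#'
#' @param hourly data.frame as returned by [aggregate_to_hours()].
#' @param min_hours minimum number of valid hours for a valid day.
#' @param tz time zone defining day boundaries; defaults to the zone of
#'   \code{hour_start}.
#' @return data.frame with columns \code{sensor_id}, \code{date},
#'   \code{pm25} and \code{n_hours}.
#' @export
aggregate_to_days <- function(hourly, min_hours = 18, tz = NULL) {
  stopifnot(is.data.frame(hourly),
            all(c("sensor_id", "hour_start", "pm25") %in% names(hourly)))
  if (is.null(tz)) {
    tz <- attr(hourly$hour_start, "tzone")
    if (is.null(tz) || identical(tz, "")) tz <- .default_tz
  }
  date <- as.Date(hourly$hour_start, tz = tz)
  key <- paste(hourly$sensor_id, date)
  ok <- !is.na(hourly$pm25)
  sums <- rowsum(ifelse(ok, hourly$pm25, 0), key)
  cnts <- rowsum(as.numeric(ok), key)

  first <- !duplicated(key)
  map <- data.frame(key = key[first],
                    sensor_id = hourly$sensor_id[first],
                    date = date[first],
                    stringsAsFactors = FALSE)
  map <- map[match(rownames(sums), map$key), ]

  n_hours <- as.integer(cnts[, 1])
  pm25 <- ifelse(n_hours >= min_hours, sums[, 1] / n_hours, NA_real_)
  out <- data.frame(sensor_id = map$sensor_id,
                    date = map$date,
                    pm25 = pm25,
                    n_hours = n_hours,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sensor_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align two time-indexed series on their common valid timestamps
#'
#' Keeps only timestamps present in both series with non-missing values in
#' both, preserving time order. All pairwise statistics (COD, pairwise R2,
#' sensor-vs-reference comparison) operate on series aligned this way.
#'
#' @param a,b data.frames with a time column and a value column.
#' @param time_col,value_col column names shared by both inputs.
#' @return data.frame with columns \code{time}, \code{x} (from \code{a}) and
#'   \code{y} (from \code{b}); zero rows (with a warning) when there is no
#'   overlap.
#' @export
align_pairwise <- function(a, b, time_col = "hour_start", value_col = "pm25") {
  stopifnot(time_col %in% names(a), time_col %in% names(b),
            value_col %in% names(a), value_col %in% names(b))
  m <- merge(
    data.frame(time = a[[time_col]], x = a[[value_col]]),
    data.frame(time = b[[time_col]], y = b[[value_col]]),
    by = "time"
  )
  m <- m[!is.na(m$x) & !is.na(m$y), , drop = FALSE]
  m <- m[order(m$time), , drop = FALSE]
  rownames(m) <- NULL
  if (nrow(m) == 0L)
    warning("no overlapping valid observations between the two series")
  m
}

#' Read a sensor observation CSV
#'
#' Expected header: \code{sensor_id,timestamp,particle_count_hppcf,pm25_ugm3}
#' with ISO-8601 timestamps. When \code{pm25_ugm3} is missing but a particle
#' count is present, the mass is filled in through the count-to-mass
#' retrieval ([count_to_mass()]).
#'
#' @param path CSV file path.
#' @param tz time zone for parsed timestamps.
#' @param coeffs [retrieval_coefficients()] used to fill mass from counts.
#' @return data.frame with columns \code{sensor_id}, \code{timestamp},
#'   \code{particle_count}, \code{pm25}.
#' @export
read_sensor_csv <- function(path, tz = .default_tz,
                            coeffs = retrieval_coefficients()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sensor_id", "timestamp", "particle_count_hppcf", "pm25_ugm3")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sensor CSV is missing columns: ", paste(missing, collapse = ", "))
  pm <- as.numeric(df$pm25_ugm3)
  cnt <- as.numeric(df$particle_count_hppcf)
  fill <- is.na(pm) & !is.na(cnt)
  if (any(fill)) pm[fill] <- count_to_mass(cnt[fill], coeffs)
  data.frame(sensor_id = as.character(df$sensor_id),
             timestamp = parse_iso8601(df$timestamp, tz),
             particle_count = cnt,
             pm25 = pm,
             stringsAsFactors = FALSE)
}

#' Write sensor observations in the canonical CSV dialect
#' @param records data.frame with \code{sensor_id}, \code{timestamp},
#'   \code{particle_count}, \code{pm25}.
#' @param path output file path.
#' @export
write_sensor_csv <- function(records, path) {
  out <- data.frame(
    sensor_id = records$sensor_id,
    timestamp = format(records$timestamp, "%Y-%m-%dT%H:%M:%S"),
    particle_count_hppcf = records$particle_count,
    pm25_ugm3 = records$pm25
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read site metadata CSV
#'
#' Expected header: \code{site_id,name,community,ej_flag,lat,lon,role}.
#' @param path CSV file path.
#' @return data.frame of sites, with latitude/longitude range checks.
#' @export
read_sites_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "name", "community", "ej_flag", "lat", "lon", "role")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("site CSV is missing columns: ", paste(missing, collapse = ", "))
  df$ej_flag <- as.logical(df$ej_flag)
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("site coordinates out of range")
  if (any(!nzchar(df$community)))
    stop("every site needs a nonempty community label")
  df
}

#' Read hourly meteorology CSV and derive humidity variables
#'
#' Expected header: \code{hour_start,temp_c,rh_pct,ws_ms,wd_deg}. Vapor
#' pressure (hPa) and dew point (degrees C) columns are added via
#' [vapor_pressure()] and [dew_point()].
#'
#' @param path CSV file path.
#' @param tz time zone for parsed timestamps.
#' @return data.frame with the input columns plus \code{vp_hpa} and
#'   \code{dew_point_c}.
#' @export
read_met_csv <- function(path, tz = .default_tz) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hour_start", "temp_c", "rh_pct", "ws_ms", "wd_deg")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("met CSV is missing columns: ", paste(missing, collapse = ", "))
  df$hour_start <- parse_iso8601(df$hour_start, tz)
  enrich_met(df)
}

#' Parse ISO-8601 timestamps
#'
#' Accepts \code{YYYY-MM-DDTHH:MM:SS} and the space-separated variant.
#' @param x character vector of timestamps.
#' @param tz time zone to interpret them in.
#' @return POSIXct vector.
#' @export
parse_iso8601 <- function(x, tz = .default_tz) {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = tz,
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) stop("unparseable timestamps in input")
  out
}
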