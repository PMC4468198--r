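## Weather-series handling: a fixed 365-day calendar, daily tmin/tmax at a
## georeferenced station, cosine sub-daily interpolation, scenario deltas.

MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_FIRST_DAY <- cumsum(c(1L, MONTH_LENGTHS[-12]))

#' Calendar month of a day-of-year (365-day calendar)
#'
#' Day 1 is 1 January; leap days are ignored throughout the package.
#'
#' @param day Integer day(s) of year in 1..365.
#' @return Month index 1..12.
#' @export
month_of_day <- function(day) {
  if (any(day < 1 | day > 365)) stop("day_of_year must be in 1..365")
  findInterval(day, MONTH_FIRST_DAY)
}

#' Daily weather series at one station
#'
#' @param station_id Label.
#' @param lon,lat Coordinates (map units or degrees; the package does no
#'   geodesy).
#' @param alt Altitude, metres above sea level (>= 0).
#' @param tmin,tmax Numeric vectors of length 365 (one per day of year),
#'   degree C, with `tmin <= tmax` everywhere.
#' @return An object of class `weather_series` with a `records`
#'   data.frame (day_of_year, tmin, tmax).
#' @export
weather_series <- function(station_id, lon, lat, alt, tmin, tmax) {
  if (length(tmin) != 365 || length(tmax) != 365)
    stop("tmin and tmax must have exactly 365 daily values")
  if (any(!is.finite(tmin)) || any(!is.finite(tmax)))
    stop("temperatures must be finite")
  if (any(tmin > tmax)) stop("tmin must not exceed tmax")
  alt <- check_num(alt, "alt")
  if (alt < 0) stop("alt must be >= 0")
  structure(list(station_id = as.character(station_id),
                 lon = check_num(lon, "lon"), lat = check_num(lat, "lat"),
                 alt = alt,
                 records = data.frame(day_of_year = 1:365,
                                      tmin = as.numeric(tmin),
                                      tmax = as.numeric(tmax))),
            class = "weather_series")
}

#' @export
print.weather_series <- function(x, ...) {
  cat("<weather_series> station ", x$station_id,
      sprintf(" (lon %.4g, lat %.4g, alt %.0f m)\n", x$lon, x$lat, x$alt),
      sprintf("  annual mean %.2f degC (daily means %.2f..%.2f)\n",
              mean(daily_means(x)), min(daily_means(x)), max(daily_means(x))),
      sep = "")
  invisible(x)
}

#' Hourly temperatures from daily extremes
#'
#' Sub-daily temperatures are inferred from the daily minimum and maximum by
#' a single full-period cosine with its maximum at 14:00 and minimum at
#' 02:00: T(h) = (tmax+tmin)/2 + ((tmax-tmin)/2) cos(2 pi (h - 14)/24).
#' The mean of the 24 hourly values equals the daily mean (tmin+tmax)/2
#' exactly.
#'
#' @param tmin,tmax Daily minimum and maximum, degree C (`tmin <= tmax`).
#' @return Numeric vector of 24 temperatures for h = 0..23.
#' @export
hourly_temperatures <- function(tmin, tmax) {
  tmin <- check_num(tmin, "tmin"); tmax <- check_num(tmax, "tmax")
  if (tmin > tmax) stop("invalid record: tmin > tmax")
  h <- 0:23
  (tmax + tmin) / 2 + (tmax - tmin) / 2 * cos(2 * pi * (h - 14) / 24)
}

#' Daily mean temperature
#'
#' @param tmin,tmax Daily extremes, degree C.
#' @return (tmin + tmax)/2, vectorised.
#' @export
daily_mean <- function(tmin, tmax) (tmin + tmax) / 2

#' Vector of 365 daily mean temperatures of a series
#'
#' @param w A [weather_series()].
#' @return Numeric vector of length 365.
#' @export
daily_means <- function(w) {
  stopifnot(inherits(w, "weather_series"))
  daily_mean(w$records$tmin, w$records$tmax)
}

#' Monthly warming deltas of a future scenario
#'
#' @param dtmin,dtmax Twelve monthly shifts (degree C) applied to daily
#'   minima and maxima respectively.
#' @return An object of class `scenario_delta`.
#' @export
scenario_delta <- function(dtmin, dtmax) {
  if (length(dtmin) != 12 || length(dtmax) != 12 ||
      any(!is.finite(dtmin)) || any(!is.finite(dtmax)))
    stop("dtmin and dtmax must be 12 finite monthly values")
  structure(list(dtmin = as.numeric(dtmin), dtmax = as.numeric(dtmax)),
            class = "scenario_delta")
}

#' Shift a weather series by monthly scenario deltas
#'
#' Each day's tmin/tmax is shifted by its calendar month's delta; station
#' metadata is unchanged.  If differing deltas ever push tmin above tmax the
#' two are swapped with a warning so the output remains a valid series.
#' Applying the negated deltas inverts the operation exactly.
#'
#' @param w A [weather_series()].
#' @param s A [scenario_delta()].
#' @return A new [weather_series()].
#' @export
apply_scenario <- function(w, s) {
  stopifnot(inherits(w, "weather_series"), inherits(s, "scenario_delta"))
  m <- month_of_day(w$records$day_of_year)
  tmin <- w$records$tmin + s$dtmin[m]
  tmax <- w$records$tmax + s$dtmax[m]
  bad <- tmin > tmax
  if (any(bad)) {
    warning(sum(bad), " day(s) had tmin > tmax after shifting; swapped")
    tmp <- tmin[bad]; tmin[bad] <- tmax[bad]; tmax[bad] <- tmp
  }
  weather_series(w$station_id, w$lon, w$lat, w$alt, tmin, tmax)
}

## CSV interfaces --------------------------------------------------------------

#' Read or write weather-series CSV files
#'
#' The CSV layout is one row per station-day with header columns
#' `station_id, lon, lat, alt_m, day_of_year, tmin_c, tmax_c`.  A file may
#' hold several stations; `read_weather()` returns a named list of
#' [weather_series()] objects in file order.
#'
#' @param path File path.
#' @param stations A list of [weather_series()] (or a single one) to write.
#' @return `read_weather()`: named list of [weather_series()];
#'   `write_weather()`: `path`, invisibly.
#' @export
read_weather <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat", "alt_m", "day_of_year",
            "tmin_c", "tmax_c")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weather CSV missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, factor(df$station_id, unique(df$station_id))),
    function(d) {
      d <- d[order(d$day_of_year), ]
      if (!identical(d$day_of_year, 1:365) &&
          !identical(as.integer(d$day_of_year), 1:365))
        stop("station ", d$station_id[1],
             ": need exactly one record per day_of_year 1..365")
      weather_series(d$station_id[1], d$lon[1], d$lat[1], d$alt_m[1],
                     d$tmin_c, d$tmax_c)
    })
  out[unique(df$station_id)]
}

#' @rdname read_weather
#' @export
write_weather <- function(stations, path) {
  if (inherits(stations, "weather_series")) stations <- list(stations)
  rows <- do.call(rbind, lapply(stations, function(w)
    data.frame(station_id = w$station_id, lon = w$lon, lat = w$lat,
               alt_m = w$alt, day_of_year = w$records$day_of_year,
               tmin_c = w$records$tmin, tmax_c = w$records$tmax)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a scenario-delta CSV
#'
#' Twelve rows with columns `month, dtmin_c, dtmax_c`.
#'
#' @param path File path.
#' @param s A [scenario_delta()] (for writing).
#' @return `read_scenario()`: a [scenario_delta()]; `write_scenario()`:
#'   `path`, invisibly.
#' @export
read_scenario <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("month", "dtmin_c", "dtmax_c")
  if (length(setdiff(need, names(df))))
    stop("scenario CSV needs columns month, dtmin_c, dtmax_c")
  df <- df[order(df$month), ]
  if (!identical(as.integer(df$month), 1:12))
    stop("scenario CSV must have months 1..12")
  scenario_delta(df$dtmin_c, df$dtmax_c)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(s, path) {
  stopifnot(inherits(s, "scenario_delta"))
  utils::write.csv(data.frame(month = 1:12, dtmin_c = s$dtmin,
                              dtmax_c = s$dtmax),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
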