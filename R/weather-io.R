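#' Construct a validated daily weather series
#'
#' A weather series is the daily minimum/maximum ambient air temperature
#' record for one site-year, the input to degree-day accumulation. It is a
#' tibble with columns `date`, `tmin`, `tmax` (degrees Celsius) carrying
#' `site_id` and `year` attributes, validated so that dates are strictly
#' increasing with no gaps and `tmin <= tmax` on every day.
#'
#' @param date `Date` vector, strictly increasing, gap-free.
#' @param tmin,tmax Daily minimum / maximum temperature in degrees Celsius.
#' @param site_id Site identifier.
#' @param year Calendar year; defaults to the year of the first date.
#' @param fill_gaps If `TRUE`, gaps of at most `max_gap` consecutive missing
#'   days are filled by linear interpolation of `tmin` and `tmax` separately;
#'   longer gaps are always an error. Default `FALSE` (reject any gap).
#' @param max_gap Largest gap (days) `fill_gaps` will bridge.
#' @return A `weather_series` tibble.
#' @export
weather_series <- function(date, tmin, tmax, site_id = "site", year = NULL,
                           fill_gaps = FALSE, max_gap = 3L) {
  if (length(date) == 0L) stop("no records")
  if (!inherits(date, "Date")) stop("`date` must be a Date vector")
  if (anyNA(date)) stop("unparseable or missing dates")
  if (length(tmin) != length(date) || length(tmax) != length(date)) {
    stop("date, tmin and tmax must have equal length")
  }
  ord <- order(date)
  date <- date[ord]; tmin <- tmin[ord]; tmax <- tmax[ord]
  if (anyDuplicated(date)) {
    stop("duplicate dates: ", paste(unique(date[duplicated(date)]), collapse = ", "))
  }
  if (anyNA(tmin) || anyNA(tmax)) stop("missing temperature values")
  bad <- which(tmin > tmax)
  if (length(bad)) {
    stop("tmin > tmax on ", paste(date[bad], collapse = ", "))
  }
  gaps <- as.integer(diff(date)) - 1L
  if (any(gaps > 0L)) {
    if (!fill_gaps) {
      i <- which(gaps > 0L)[1L]
      stop("missing days between ", date[i], " and ", date[i + 1L],
           " (use fill_gaps = TRUE for gaps <= ", max_gap, " days)")
    }
    if (any(gaps > max_gap)) {
      i <- which(gaps > max_gap)[1L]
      stop("gap of ", gaps[i], " days between ", date[i], " and ",
           date[i + 1L], " exceeds max_gap = ", max_gap)
    }
    full <- seq(date[1L], date[length(date)], by = "day")
    tmin <- stats::approx(as.numeric(date), tmin, xout = as.numeric(full))$y
    tmax <- stats::approx(as.numeric(date), tmax, xout = as.numeric(full))$y
    date <- full
  }
  if (is.null(year)) year <- as.integer(format(date[1L], "%Y"))
  out <- tibble::tibble(date = date, tmin = tmin, tmax = tmax)
  structure(out, site_id = site_id, year = as.integer(year),
            class = c("weather_series", class(out)))
}

#' Read a daily weather CSV
#'
#' Expects a header `date,tmin,tmax` with ISO-8601 dates. Fahrenheit input is
#' converted to the internal Celsius representation via C = (F - 32) * 5/9.
#'
#' @param path Path to the CSV file.
#' @param unit `"celsius"` or `"fahrenheit"` (the unit of `tmin`/`tmax`).
#' @inheritParams weather_series
#' @return A [weather_series] in degrees Celsius.
#' @export
read_weather_csv <- function(path, unit = c("celsius", "fahrenheit"),
                             site_id = NULL, fill_gaps = FALSE, max_gap = 3L) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no records in ", path)
  date <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  if (anyNA(date)) {
    stop("unparseable date on row ", which(is.na(date))[1L], " of ", path)
  }
  tmin <- as.numeric(df$tmin); tmax <- as.numeric(df$tmax)
  if (unit == "fahrenheit") {
    tmin <- f_to_c(tmin); tmax <- f_to_c(tmax)
  }
  if (is.null(site_id)) site_id <- sub("\\.csv$", "", basename(path))
  weather_series(date, tmin, tmax, site_id = site_id,
                 fill_gaps = fill_gaps, max_gap = max_gap)
}

#' Write a weather series to CSV
#'
#' Inverse of [read_weather_csv()]: header `date,tmin,tmax`, ISO dates,
#' degrees Celsius.
#'
#' @param series A [weather_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(series, path) {
  df <- data.frame(date = format(series$date, "%Y-%m-%d"),
                   tmin = series$tmin, tmax = series$tmax)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate sub-daily temperature readings to daily extremes
#'
#' Reduces a stream of timestamped readings (e.g. a logger sampling every two
#' hours) to per-calendar-day minimum and maximum temperature.
#'
#' @param readings A data frame with columns `timestamp` (`POSIXct` or
#'   anything `as.Date()` accepts) and `temperature` (degrees Celsius).
#' @inheritParams weather_series
#' @return A [weather_series].
#' @export
aggregate_subdaily_to_daily <- function(readings, site_id = "site") {
  if (!all(c("timestamp", "temperature") %in% names(readings))) {
    stop("readings must have columns `timestamp` and `temperature`")
  }
  if (nrow(readings) == 0L) stop("no records")
  day <- as.Date(readings$timestamp)
  tmin <- tapply(readings$temperature, day, min)
  tmax <- tapply(readings$temperature, day, max)
  dates <- as.Date(names(tmin))
  o <- order(dates)
  # a day with zero readings inside the span shows up as a gap here
  weather_series(dates[o], as.numeric(tmin)[o], as.numeric(tmax)[o],
                 site_id = site_id)
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> site %s, year %d: %d days (%s to %s)\n",
              attr(x, "site_id"), attr(x, "year"), nrow(x),
              format(x$date[1L]), format(x$date[nrow(x)])))
  NextMethod()
}
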