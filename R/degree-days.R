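#' Degree-day model parameters
#'
#' Bundles the degree-day calculation method, the lower and upper
#' developmental thresholds, and the biofix (accumulation start date).
#'
#' The `simple` method is the classic method-1 average: the mean of the daily
#' extremes minus the lower threshold, floored at zero, with a horizontal
#' cutoff at the upper threshold (the effective mean is capped at `upper`;
#' the extremes themselves are never clamped before averaging). The `sine`
#' method fits a half-day sine wave through the daily extremes and integrates
#' the area between the thresholds, per half-day.
#'
#' @param method `"simple"` or `"sine"`.
#' @param lower,upper Lower and upper developmental thresholds in degrees
#'   Celsius; accumulation is zero below `lower` and capped above `upper`.
#' @param biofix Accumulation start: an `"MM-DD"` string resolved per year
#'   (leap-year safe), or an integer Julian day used literally in all years.
#' @param sine_second_half `"next_day_tmin"` (double-sine convention: the
#'   second half-day runs from the day's maximum down to the following day's
#'   minimum) or `"same_day_tmin"` (single-sine: both half-days use the same
#'   day's extremes).
#' @return A `dd_params` object.
#' @examples
#' dd_params("simple", lower = 15, upper = 21.7, biofix = "01-01")
#' @export
dd_params <- function(method = c("simple", "sine"), lower, upper,
                      biofix = "01-01",
                      sine_second_half = c("next_day_tmin", "same_day_tmin")) {
  method <- match.arg(method)
  sine_second_half <- match.arg(sine_second_half)
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1L ||
      length(upper) != 1L) {
    stop("thresholds must be single numeric values")
  }
  if (!(lower < upper)) stop("lower threshold must be below upper threshold")
  structure(list(method = method, lower = lower, upper = upper,
                 biofix = biofix, sine_second_half = sine_second_half),
            class = "dd_params")
}

#' @export
print.dd_params <- function(x, ...) {
  cat(sprintf("<dd_params> %s method, thresholds %.2f/%.2f degC, biofix %s\n",
              x$method, x$lower, x$upper,
              if (is.numeric(x$biofix)) paste("Julian", x$biofix) else x$biofix))
  invisible(x)
}

#' Daily degree-days by the simple average method
#'
#' Method-1 average: with `t_avg = (tmin + tmax)/2`, the day contributes 0 if
#' `t_avg <= lower`, `upper - lower` if `t_avg >= upper` (horizontal cutoff),
#' and `t_avg - lower` otherwise. The extremes are never pre-clamped.
#' Vectorised over all arguments.
#'
#' @param tmin,tmax Daily extremes, degrees Celsius, `tmin <= tmax`.
#' @param lower,upper Developmental thresholds, `lower < upper`.
#' @return Degree-days in `[0, upper - lower]`.
#' @examples
#' simple_daily_dd(10, 30, 15, 21.7)  # mean 20 -> 5
#' @export
simple_daily_dd <- function(tmin, tmax, lower, upper) {
  if (any(tmin > tmax)) stop("tmin > tmax")
  if (any(lower >= upper)) stop("lower threshold must be below upper threshold")
  t_avg <- (tmin + tmax) / 2
  pmax(0, pmin(t_avg, upper) - lower)
}

#' Half-day degree-days by the sine-wave method
#'
#' Models a half day as `T(theta) = m + a * sin(theta)` for `theta` in
#' `[-pi/2, pi/2]`, with midpoint `m = (t_low + t_high)/2` and amplitude
#' `a = (t_high - t_low)/2`, and returns the thresholded thermal area
#' `(1/(2*pi)) * integral of max(0, min(T, upper) - lower)`. Closed form over
#' the six threshold/extreme configurations; a constant trace (`a = 0`)
#' degenerates to half the clamped excess. Vectorised.
#'
#' @param t_low,t_high Temperatures bounding the half-day, `t_low <= t_high`.
#' @inheritParams simple_daily_dd
#' @return Degree-days in `[0, (upper - lower)/2]`.
#' @export
sine_half_day_dd <- function(t_low, t_high, lower, upper) {
  if (any(t_low > t_high)) stop("t_low > t_high")
  if (any(lower >= upper)) stop("lower threshold must be below upper threshold")
  n <- max(length(t_low), length(t_high), length(lower), length(upper))
  t_low <- rep_len(t_low, n); t_high <- rep_len(t_high, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  m <- (t_low + t_high) / 2
  a <- (t_high - t_low) / 2
  out <- numeric(n)

  flat <- a == 0
  below <- !flat & t_high <= lower
  above <- !flat & t_low >= upper
  inside <- !flat & !below & !above & t_low >= lower & t_high <= upper
  cross_lo <- !flat & !below & !above & t_low < lower & t_high <= upper
  cross_hi <- !flat & !below & !above & t_low >= lower & t_high > upper
  cross_both <- !flat & !below & !above & t_low < lower & t_high > upper

  out[flat] <- 0.5 * pmax(0, pmin(m[flat], upper[flat]) - lower[flat])
  out[below] <- 0
  out[above] <- (upper[above] - lower[above]) / 2
  out[inside] <- (m[inside] - lower[inside]) / 2
  if (any(cross_lo)) {
    i <- cross_lo
    th1 <- asin(pmax(-1, pmin(1, (lower[i] - m[i]) / a[i])))
    out[i] <- ((m[i] - lower[i]) * (pi / 2 - th1) + a[i] * cos(th1)) / (2 * pi)
  }
  if (any(cross_hi)) {
    i <- cross_hi
    th2 <- asin(pmax(-1, pmin(1, (upper[i] - m[i]) / a[i])))
    out[i] <- ((m[i] - lower[i]) * (th2 + pi / 2) - a[i] * cos(th2) +
                 (upper[i] - lower[i]) * (pi / 2 - th2)) / (2 * pi)
  }
  if (any(cross_both)) {
    i <- cross_both
    th1 <- asin(pmax(-1, pmin(1, (lower[i] - m[i]) / a[i])))
    th2 <- asin(pmax(-1, pmin(1, (upper[i] - m[i]) / a[i])))
    out[i] <- ((m[i] - lower[i]) * (th2 - th1) +
                 a[i] * (cos(th1) - cos(th2)) +
                 (upper[i] - lower[i]) * (pi / 2 - th2)) / (2 * pi)
  }
  out
}

#' Daily degree-days by the half-day sine-wave method
#'
#' The day is the sum of two half-days: the first rises from the day's
#' minimum to its maximum; the second falls from the maximum to the next
#' day's minimum (double-sine convention) or back to the same day's minimum
#' (single-sine). On the final day of a series, where no following minimum
#' exists, the day's own minimum is reused.
#'
#' @inheritParams simple_daily_dd
#' @param next_tmin Following day's minimum (degrees Celsius); `NA` entries
#'   fall back to the same day's `tmin`.
#' @return Degree-days in `[0, upper - lower]`. Vectorised.
#' @export
sine_daily_dd <- function(tmin, tmax, next_tmin = NA_real_, lower, upper) {
  if (any(tmin > tmax)) stop("tmin > tmax")
  n <- max(length(tmin), length(tmax), length(next_tmin))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n)
  next_tmin <- rep_len(next_tmin, n)
  next_tmin[is.na(next_tmin)] <- tmin[is.na(next_tmin)]
  # second half-day endpoints kept ordered even if the next morning is
  # warmer than today's maximum
  lo2 <- pmin(next_tmin, tmax)
  hi2 <- pmax(next_tmin, tmax)
  sine_half_day_dd(tmin, tmax, lower, upper) +
    sine_half_day_dd(lo2, hi2, lower, upper)
}

#' Accumulate degree-days over a weather series
#'
#' Computes daily degree-days under `params` from the biofix to the end of
#' the series, and their running sum. Accumulation is zero on the day before
#' the biofix; `cumulative_dd[k]` is the total at the end of day `k`.
#'
#' @param series A [weather_series] covering the biofix date onwards.
#' @param params A [dd_params].
#' @return An `accumulation_series` tibble with columns `date`, `daily_dd`,
#'   `cumulative_dd`, carrying the series' `site_id`/`year` attributes.
#' @export
accumulate_degree_days <- function(series, params) {
  stopifnot(inherits(params, "dd_params"))
  year <- attr(series, "year")
  start <- resolve_start_date(params$biofix, year)
  if (series$date[1L] > start) {
    stop("weather series starts ", series$date[1L],
         ", after the biofix ", start)
  }
  keep <- series$date >= start
  dates <- series$date[keep]
  tmin <- series$tmin[keep]
  tmax <- series$tmax[keep]
  if (length(dates) == 0L) stop("weather series ends before the biofix")
  daily <- if (params$method == "simple") {
    simple_daily_dd(tmin, tmax, params$lower, params$upper)
  } else {
    nxt <- if (params$sine_second_half == "next_day_tmin") {
      c(tmin[-1L], NA_real_)
    } else {
      tmin
    }
    sine_daily_dd(tmin, tmax, nxt, params$lower, params$upper)
  }
  out <- tibble::tibble(date = dates, daily_dd = daily,
                        cumulative_dd = cumsum(daily))
  structure(out, site_id = attr(series, "site_id"), year = year,
            class = c("accumulation_series", class(out)))
}

#' Date at which a degree-day total is reached
#'
#' Returns the (fractional) Julian day at which the cumulative accumulation
#' first reaches `target`. Within the crossing day the date is linearly
#' interpolated (the default), or rounded up to the end of the first crossing
#' day with `interpolate = FALSE`. A target never reached within the series
#' returns `NA` — a "not reached" signal, not an error.
#'
#' @param acc An `accumulation_series` from [accumulate_degree_days()].
#' @param target Degree-day total, `>= 0`.
#' @param interpolate Interpolate within the crossing day?
#' @return Fractional Julian day-of-year (numeric), or `NA_real_` if the
#'   target is never reached.
#' @export
date_at_dd <- function(acc, target, interpolate = TRUE) {
  if (!is.numeric(target) || length(target) != 1L || is.na(target) ||
      target < 0) {
    stop("`target` must be a single non-negative number")
  }
  jd <- julian_day(acc$date)
  if (target == 0) return(as.numeric(jd[1L]))
  k <- match(TRUE, acc$cumulative_dd >= target)
  if (is.na(k)) return(NA_real_)
  if (!interpolate) return(as.numeric(jd[k]))
  prev <- if (k == 1L) 0 else acc$cumulative_dd[k - 1L]
  frac <- (target - prev) / acc$daily_dd[k]
  jd[k] - 1 + frac
}
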