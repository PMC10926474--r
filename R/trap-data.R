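#' Read raw trap observations from CSV
#'
#' Expects a header `site,date,trap,quantity`. Quantities may be beetle
#' counts or sample volumes (ml); only proportions of the seasonal total
#' enter the model, so the two are interchangeable.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated observations with columns `site`, `date`,
#'   `trap`, `quantity`.
#' @export
read_trap_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "date", "trap", "quantity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no records in ", path)
  date <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  if (anyNA(date)) {
    stop("unparseable date on row ", which(is.na(date))[1L], " of ", path)
  }
  qty <- as.numeric(df$quantity)
  bad <- which(is.na(qty) | qty < 0)
  if (length(bad)) {
    stop("negative or missing quantity on row ", bad[1L],
         " (", df$site[bad[1L]], ", ", df$date[bad[1L]], ")")
  }
  key <- paste(df$site, df$date, df$trap, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate (site, date, trap) observation: ",
         df$site[d], ", ", df$date[d], ", trap ", df$trap[d])
  }
  tibble::tibble(site = as.character(df$site), date = date,
                 trap = as.character(df$trap), quantity = qty)
}

#' Reduce trap observations to a cumulative trap-catch proportion curve
#'
#' Pools all traps within each observation date by summing quantities, then
#' divides the running total by the seasonal total, yielding the cumulative
#' proportion of seasonal catch per observation date — the dependent variable
#' of the emergence model. Proportions are invariant to how catch is split
#' across traps on a date.
#'
#' @param observations A tibble as returned by [read_trap_csv()] (columns
#'   `date` and `quantity` required; `site` optional) for one site-year.
#' @param site_id,year Identifiers; inferred from the data when omitted.
#' @return A `site_year_curve` tibble with columns `date`,
#'   `interval_quantity`, `cumulative_proportion`.
#' @export
build_curve <- function(observations, site_id = NULL, year = NULL) {
  if (nrow(observations) == 0L) stop("no observations")
  if (is.null(site_id)) {
    site_id <- if ("site" %in% names(observations)) {
      unique(observations$site)[1L]
    } else "site"
  }
  if (any(observations$quantity < 0)) stop("negative quantity")
  qty <- tapply(observations$quantity, observations$date, sum)
  dates <- as.Date(names(qty))
  o <- order(dates)
  dates <- dates[o]; qty <- as.numeric(qty)[o]
  if (length(dates) < 2L) stop("need at least 2 observation dates")
  total <- sum(qty)
  if (total <= 0) stop("no catch: seasonal total is zero")
  if (is.null(year)) year <- as.integer(format(dates[1L], "%Y"))
  out <- tibble::tibble(date = dates, interval_quantity = qty,
                        cumulative_proportion = cumsum(qty) / total)
  structure(out, site_id = site_id, year = as.integer(year),
            season_total = total,
            class = c("site_year_curve", class(out)))
}

#' @export
print.site_year_curve <- function(x, ...) {
  cat(sprintf("<site_year_curve> site %s, year %d: %d dates, season total %g\n",
              attr(x, "site_id"), attr(x, "year"), nrow(x),
              attr(x, "season_total")))
  NextMethod()
}

#' Observed date at a target cumulative trap-catch proportion
#'
#' Linearly interpolates the observed cumulative-proportion curve to the date
#' at which proportion `p` was reached. By default interpolation is on the
#' calendar-day axis; with `axis = "degree-day"` it is done on the
#' accumulated degree-day axis of `acc` and the crossing is mapped back to a
#' date through [date_at_dd()].
#'
#' If the very first observation already exceeds `p` the first observation
#' date is returned with a censoring warning (the true crossing happened
#' before monitoring began).
#'
#' @param curve A [build_curve()] result.
#' @param p Target proportion in (0, 1).
#' @param axis Interpolation axis: `"day"` (default) or `"degree-day"`.
#' @param acc An `accumulation_series` for the same site-year; required for
#'   the degree-day axis.
#' @return Fractional Julian day-of-year (numeric).
#' @export
observed_date_at_proportion <- function(curve, p,
                                        axis = c("day", "degree-day"),
                                        acc = NULL) {
  axis <- match.arg(axis)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("`p` must be a single proportion strictly between 0 and 1")
  }
  cp <- curve$cumulative_proportion
  jd <- julian_day(curve$date)
  k <- match(TRUE, cp >= p)
  if (is.na(k)) stop("curve never reaches proportion ", p)
  if (cp[k] == p) {
    if (axis == "day") return(as.numeric(jd[k]))
  }
  if (k == 1L) {
    warning("first observation already at or above p = ", p,
            "; returning first observation date (left-censored)")
    return(as.numeric(jd[1L]))
  }
  if (axis == "day") {
    jd[k - 1L] + (p - cp[k - 1L]) / (cp[k] - cp[k - 1L]) * (jd[k] - jd[k - 1L])
  } else {
    if (is.null(acc)) stop("degree-day axis requires `acc`")
    dd <- dd_at_observation_dates(acc, curve$date)
    d_cross <- dd[k - 1L] +
      (p - cp[k - 1L]) / (cp[k] - cp[k - 1L]) * (dd[k] - dd[k - 1L])
    date_at_dd(acc, d_cross)
  }
}

# Cumulative degree-days at each observation date (end-of-day totals).
dd_at_observation_dates <- function(acc, dates) {
  idx <- match(as.Date(dates), acc$date)
  if (anyNA(idx)) {
    stop("observation date(s) outside the accumulation series: ",
         paste(dates[is.na(idx)], collapse = ", "))
  }
  acc$cumulative_dd[idx]
}
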