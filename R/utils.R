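#' Convert temperatures between Fahrenheit and Celsius
#'
#' @param x Numeric vector of temperatures.
#' @return Numeric vector of converted temperatures.
#' @examples
#' f_to_c(59)  # 15
#' c_to_f(21.7)
#' @export
f_to_c <- function(x) (x - 32) * 5 / 9

#' @rdname f_to_c
#' @export
c_to_f <- function(x) x * 9 / 5 + 32

#' Day-of-year (Julian day) helpers
#'
#' `julian_day()` maps a calendar date to its day-of-year index (Jan 1 = 1);
#' `julian_to_date()` inverts it for a given year, accepting fractional days
#' (the fraction is kept by returning a numeric date offset when fractional).
#'
#' @param date A `Date` vector.
#' @param jd Numeric day-of-year (may be fractional).
#' @param year Integer calendar year.
#' @return `julian_day()`: integer vector. `julian_to_date()`: a `Date`
#'   (fractional days are floored to the containing calendar day).
#' @export
julian_day <- function(date) {
  as.integer(format(date, "%j"))
}

#' @rdname julian_day
#' @export
julian_to_date <- function(jd, year) {
  as.Date(paste0(year, "-01-01")) + (floor(jd) - 1)
}

# Resolve a biofix specification to a concrete Date within `year`.
# Accepts "MM-DD" strings (calendar mode, leap-year safe) or an integer
# Julian index (literal-Julian mode, e.g. the fixed {1, 32, 50, 91} set).
resolve_start_date <- function(start, year) {
  if (is.character(start)) {
    d <- as.Date(paste0(year, "-", start))
    if (is.na(d)) stop("invalid biofix 'MM-DD' specification: ", start)
    d
  } else if (is.numeric(start)) {
    if (start < 1 || start > 366) stop("Julian biofix must be in 1..366")
    as.Date(paste0(year, "-01-01")) + (as.integer(start) - 1)
  } else {
    stop("biofix must be an 'MM-DD' string or a Julian day number")
  }
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
# seed = NULL draws from the current stream untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
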