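# Independent oracles and fixture builders shared across test files.

# Numerical quadrature of the thresholded half-day sine trace:
# (1/(2*pi)) * integral over theta in [-pi/2, pi/2] of
# max(0, min(m + a*sin(theta), upper) - lower). Midpoint rule.
quadrature_half_day_dd <- function(t_low, t_high, lower, upper,
                                   n_points = 2e5) {
  m <- (t_low + t_high) / 2
  a <- (t_high - t_low) / 2
  h <- pi / n_points
  theta <- seq(-pi / 2 + h / 2, pi / 2 - h / 2, by = h)
  tt <- m + a * sin(theta)
  sum(pmax(0, pmin(tt, upper) - lower)) * h / (2 * pi)
}

# Second, independent implementation of Lin's concordance from the defining
# formula (kept deliberately verbose and separate from the package's).
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Build vectors with exact population Pearson correlation r and exact
# location/scale structure giving accuracy A (equal variances, mean shift).
# Used to reconstruct agreement statistics from printed components.
vectors_with_r_and_A <- function(r, A, n = 200) {
  stopifnot(abs(r) <= 1, A > 0, A <= 1)
  t <- seq(0, 2 * pi * (n - 1) / n, length.out = n)
  z1 <- sqrt(2) * cos(t)   # population mean 0, var 1
  z2 <- sqrt(2) * sin(t)   # exactly uncorrelated with z1, var 1
  x <- z1
  y <- r * z1 + sqrt(1 - r^2) * z2
  # equal unit variances: A = 2 / (2 + d^2) with d the mean difference
  d <- sqrt(2 / A - 2)
  list(x = x, y = y + d)
}

# Constant-weather series: handy deterministic accumulation fixture.
make_constant_weather <- function(tmin, tmax, year = 2020,
                                  from = paste0(year, "-01-01"),
                                  to = paste0(year, "-12-31"),
                                  site_id = "const") {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  weather_series(dates, rep(tmin, length(dates)), rep(tmax, length(dates)),
                 site_id = site_id, year = year)
}

# A small deterministic trap-catch curve fixture.
make_curve <- function(quantities, dates, site_id = "fix", year = NULL) {
  obs <- tibble::tibble(site = site_id, date = as.Date(dates),
                        trap = "T1", quantity = quantities)
  build_curve(obs, site_id = site_id, year = year)
}

# Randomized (t_low, t_high, lower, upper) cases stratified to cover all six
# sine-method branch configurations.
sample_sine_cases <- function(n_per_branch, seed = 421) {
  set.seed(seed)
  out <- list()
  k <- 0L
  branches <- c("below", "above", "inside", "cross_lo", "cross_hi", "both")
  while (k < n_per_branch * length(branches)) {
    lower <- runif(1, 0, 15)
    upper <- lower + runif(1, 2, 22)
    t_low <- runif(1, -15, 40)
    t_high <- t_low + runif(1, 0, 25)
    br <- if (t_high <= lower) "below"
      else if (t_low >= upper) "above"
      else if (t_low >= lower && t_high <= upper) "inside"
      else if (t_low < lower && t_high <= upper) "cross_lo"
      else if (t_low >= lower && t_high > upper) "cross_hi"
      else "both"
    have <- sum(vapply(out, function(cs) cs$branch == br, logical(1L)))
    if (have >= n_per_branch) next
    k <- k + 1L
    out[[k]] <- list(t_low = t_low, t_high = t_high, lower = lower,
                     upper = upper, branch = br)
  }
  out
}
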