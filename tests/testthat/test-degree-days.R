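test_that("simple average method handles thresholds with horizontal cutoff", {
  expect_equal(simple_daily_dd(15, 15, 15, 21.7), 0)
  expect_equal(simple_daily_dd(10, 30, 15, 21.7), 5)
  expect_equal(simple_daily_dd(25, 35, 15, 21.7), 6.7)
  expect_error(simple_daily_dd(20, 10, 15, 21.7), "tmin > tmax")
})

test_that("sine half-day handles the saturated and degenerate traces", {
  expect_equal(sine_half_day_dd(5, 14, 15, 21.7), 0)
  expect_equal(sine_half_day_dd(14, 14, 15, 21.7), 0)
  expect_equal(sine_half_day_dd(25, 30, 15, 21.7), (21.7 - 15) / 2)
  # constant trace between thresholds: half the excess
  expect_equal(sine_half_day_dd(18, 18, 15, 21.7), 1.5)
  expect_equal(
    sine_half_day_dd(10, 30, 15, 21.7),
    quadrature_half_day_dd(10, 30, 15, 21.7),
    tolerance = 1e-6
  )
})

test_that("sine closed form matches the quadrature oracle on all six branches", {
  cases <- sample_sine_cases(n_per_branch = 170)  # > 1000 cases total
  branches_seen <- character(0)
  for (cs in cases) {
    closed <- sine_half_day_dd(cs$t_low, cs$t_high, cs$lower, cs$upper)
    oracle <- quadrature_half_day_dd(cs$t_low, cs$t_high, cs$lower, cs$upper)
    expect_lt(abs(closed - oracle), 1e-6)
    branches_seen <- union(branches_seen, cs$branch)
  }
  expect_setequal(branches_seen,
                  c("below", "above", "inside", "cross_lo", "cross_hi", "both"))
})

test_that("sine daily value composes two half-days correctly", {
  # constant 18 degC accumulates 3 per day against 15/21.7
  expect_equal(sine_daily_dd(18, 18, 18, 15, 21.7), 3)
  # symmetric configuration doubles one half-day
  expect_equal(sine_daily_dd(10, 30, 10, 15, 21.7),
               2 * sine_half_day_dd(10, 30, 15, 21.7))
  # mixed half-days vs per-half-day quadrature
  expect_equal(
    sine_daily_dd(10, 30, 16, 15, 21.7),
    quadrature_half_day_dd(10, 30, 15, 21.7) +
      quadrature_half_day_dd(16, 30, 15, 21.7),
    tolerance = 2e-6
  )
})

test_that("simple and sine agree when the trace stays between thresholds", {
  set.seed(5)
  for (i in 1:50) {
    lower <- runif(1, 0, 10)
    upper <- lower + runif(1, 8, 20)
    tmin <- runif(1, lower, upper)
    tmax <- runif(1, tmin, upper)
    expect_equal(sine_daily_dd(tmin, tmax, tmin, lower, upper),
                 (tmin + tmax) / 2 - lower)
    expect_equal(simple_daily_dd(tmin, tmax, lower, upper),
                 (tmin + tmax) / 2 - lower)
  }
})

test_that("daily values are capped and monotone in the threshold window", {
  set.seed(9)
  for (i in 1:200) {
    lower <- runif(1, 0, 15)
    upper <- lower + runif(1, 1, 22)
    tmin <- runif(1, -15, 40)
    tmax <- tmin + runif(1, 0, 25)
    s <- simple_daily_dd(tmin, tmax, lower, upper)
    w <- sine_daily_dd(tmin, tmax, NA, lower, upper)
    expect_gte(s, 0); expect_lte(s, upper - lower + 1e-12)
    expect_gte(w, 0); expect_lte(w, upper - lower + 1e-12)
    # widening the window never decreases the daily value
    s2 <- simple_daily_dd(tmin, tmax, lower - 1, upper + 1)
    w2 <- sine_daily_dd(tmin, tmax, NA, lower - 1, upper + 1)
    expect_gte(s2, s - 1e-12)
    expect_gte(w2, w - 1e-12)
  }
})

test_that("accumulation saturates, is monotone, and matches day-by-day recomputation", {
  p <- dd_params("simple", lower = 15, upper = 21.7, biofix = "01-01")
  hot <- make_constant_weather(25, 35, from = "2020-01-01", to = "2020-01-10")
  acc <- accumulate_degree_days(hot, p)
  expect_equal(acc$cumulative_dd[10], 10 * 6.7)

  set.seed(31)
  dates <- seq(as.Date("2020-06-01"), by = "day", length.out = 30)
  tmin <- runif(30, 5, 20)
  tmax <- tmin + runif(30, 0, 15)
  ws <- weather_series(dates, tmin, tmax, year = 2020)
  for (method in c("simple", "sine")) {
    pm <- dd_params(method, lower = 12, upper = 24, biofix = "06-01")
    acc <- accumulate_degree_days(ws, pm)
    expect_true(all(diff(acc$cumulative_dd) >= 0))
    # independent day-by-day loop over single-day calls
    brute <- numeric(30)
    for (k in 1:30) {
      brute[k] <- if (method == "simple") {
        simple_daily_dd(tmin[k], tmax[k], 12, 24)
      } else {
        nxt <- if (k < 30) tmin[k + 1] else tmin[k]
        sine_daily_dd(tmin[k], tmax[k], nxt, 12, 24)
      }
    }
    expect_equal(acc$daily_dd, brute)
    expect_equal(acc$cumulative_dd, cumsum(brute))
  }

  late <- weather_series(dates, tmin, tmax, year = 2020)
  expect_error(
    accumulate_degree_days(late, dd_params("simple", 15, 21.7, biofix = "01-01")),
    "after the biofix"
  )
})

test_that("biofix resolves per calendar year including leap years", {
  p_mar <- dd_params("simple", lower = 0, upper = 30, biofix = "03-01")
  w20 <- make_constant_weather(10, 20, year = 2020)  # leap year
  w21 <- make_constant_weather(10, 20, year = 2021)
  expect_equal(julian_day(accumulate_degree_days(w20, p_mar)$date[1]), 61L)
  expect_equal(julian_day(accumulate_degree_days(w21, p_mar)$date[1]), 60L)
  # literal-Julian mode pins the index in all years
  p_jul <- dd_params("simple", lower = 0, upper = 30, biofix = 60)
  expect_equal(julian_day(accumulate_degree_days(w20, p_jul)$date[1]), 60L)
  expect_equal(julian_day(accumulate_degree_days(w21, p_jul)$date[1]), 60L)
})

test_that("date_at_dd interpolates within the crossing day", {
  p <- dd_params("simple", lower = 15, upper = 30, biofix = "01-01")
  # constant 5 DD/day (mean 20 vs lower 15)
  ws <- make_constant_weather(15, 25, year = 2021)
  acc <- accumulate_degree_days(ws, p)
  expect_equal(date_at_dd(acc, 0), 1)
  expect_equal(date_at_dd(acc, 50), 10)
  expect_equal(date_at_dd(acc, 52.5), 10.5)
  expect_equal(date_at_dd(acc, 50, interpolate = FALSE), 10)
  expect_equal(date_at_dd(acc, 51, interpolate = FALSE), 11)
  expect_true(is.na(date_at_dd(acc, 1e6)))

  # random series, random targets vs a brute-force scan + interpolation
  set.seed(77)
  dates <- seq(as.Date("2021-04-01"), by = "day", length.out = 120)
  tmin <- runif(120, 2, 18); tmax <- tmin + runif(120, 0, 14)
  ws2 <- weather_series(dates, tmin, tmax, year = 2021)
  acc2 <- accumulate_degree_days(ws2,
    dd_params("simple", lower = 10, upper = 25, biofix = "04-01"))
  jd <- julian_day(acc2$date)
  targets <- runif(100, 0.01, max(acc2$cumulative_dd))
  for (tg in targets) {
    k <- which(acc2$cumulative_dd >= tg)[1]
    prev <- if (k == 1) 0 else acc2$cumulative_dd[k - 1]
    oracle <- jd[k] - 1 + (tg - prev) / acc2$daily_dd[k]
    expect_equal(date_at_dd(acc2, tg), oracle)
  }
})
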