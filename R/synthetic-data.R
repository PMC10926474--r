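#' Synthetic weather generator configuration
#'
#' Parameters of the daily min/max temperature simulator: a sinusoidal
#' seasonal cycle in the daily mean plus AR(1) noise, with a constant diurnal
#' range split symmetrically about the mean. Defaults emulate an upper
#' Midwest (Minnesota-like) temperate climate in which a 15 degC lower
#' developmental threshold puts the 10% trap-catch date in late June-July.
#'
#' @param annual_mean Annual mean temperature, degC.
#' @param seasonal_amplitude Half peak-to-trough seasonal swing, degC.
#' @param peak_day Julian day of the warmest mean.
#' @param diurnal_range `tmax - tmin`, degC, held constant.
#' @param noise_sd Standard deviation of daily AR(1) innovations, degC.
#' @param noise_autocorrelation Lag-1 coefficient in `[0, 1)`; positive values
#'   create the multi-day warm spells real accumulation runs exhibit.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A `weather_gen_config` list.
#' @export
weather_gen_config <- function(annual_mean = 7, seasonal_amplitude = 16,
                               peak_day = 200, diurnal_range = 10,
                               noise_sd = 3, noise_autocorrelation = 0.6,
                               seed = NULL) {
  stopifnot(seasonal_amplitude >= 0, diurnal_range >= 0, noise_sd >= 0,
            noise_autocorrelation >= 0, noise_autocorrelation < 1)
  structure(list(annual_mean = annual_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 peak_day = peak_day, diurnal_range = diurnal_range,
                 noise_sd = noise_sd,
                 noise_autocorrelation = noise_autocorrelation,
                 seed = seed),
            class = "weather_gen_config")
}

#' Generate a synthetic full-year daily weather series
#'
#' Daily mean temperature follows
#' `annual_mean + seasonal_amplitude * sin(2*pi*(d - peak_day + 91.25)/365.25)`
#' plus AR(1) noise (`e_d = rho * e_{d-1} + innovation`, innovations Normal
#' with `noise_sd`, stationary start); `tmin`/`tmax` sit half a diurnal range
#' below/above the noisy mean. Reproducible from the config seed.
#'
#' @param config A [weather_gen_config()].
#' @param year Calendar year (leap years give 366 days).
#' @param site_id Site identifier for the resulting series.
#' @return A [weather_series] covering the full calendar year.
#' @export
generate_weather <- function(config, year, site_id = "synthetic") {
  stopifnot(inherits(config, "weather_gen_config"))
  dates <- seq(as.Date(paste0(year, "-01-01")),
               as.Date(paste0(year, "-12-31")), by = "day")
  d <- seq_along(dates)
  mean_t <- config$annual_mean + config$seasonal_amplitude *
    sin(2 * pi * (d - config$peak_day + 91.25) / 365.25)
  noise <- with_local_seed(config$seed, {
    rho <- config$noise_autocorrelation
    innov <- stats::rnorm(length(d), sd = config$noise_sd)
    e <- numeric(length(d))
    # stationary initial condition so early-season noise is not deflated
    e[1L] <- if (config$noise_sd > 0) {
      stats::rnorm(1L, sd = config$noise_sd / sqrt(1 - rho^2))
    } else 0
    for (k in seq_along(d)[-1L]) e[k] <- rho * e[k - 1L] + innov[k]
    e
  })
  daily <- mean_t + noise
  weather_series(dates, daily - config$diurnal_range / 2,
                 daily + config$diurnal_range / 2,
                 site_id = site_id, year = year)
}

#' Synthetic trap-catch generator configuration
#'
#' Defines the true data-generating process for trap observations: a known
#' degree-day model and emergence curve, a trap-visit schedule, and the
#' seasonal catch size with its sampling noise.
#'
#' @param true_params The generating [dd_params()].
#' @param true_curve The generating [emergence_curve()].
#' @param first_obs_day Julian day of the first trap visit (default 150,
#'   late-May deployment, ahead of emergence).
#' @param obs_interval Days between visits; 3.5 approximates twice-weekly
#'   collection (alternating 3/4-day intervals), 7 is weekly.
#' @param season_total Expected seasonal catch per site-year.
#' @param count_noise `"multinomial"` (fixed seasonal total split across
#'   intervals) or `"poisson"` (independent interval counts).
#' @param n_traps Number of trap ids the catch is split across.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A `trap_gen_config` list.
#' @export
trap_gen_config <- function(true_params, true_curve, first_obs_day = 150,
                            obs_interval = 3.5, season_total = 10000,
                            count_noise = c("multinomial", "poisson"),
                            n_traps = 4L, seed = NULL) {
  stopifnot(inherits(true_params, "dd_params"),
            inherits(true_curve, "emergence_curve"),
            obs_interval > 0, season_total > 0, n_traps >= 1L)
  count_noise <- match.arg(count_noise)
  structure(list(true_params = true_params, true_curve = true_curve,
                 first_obs_day = first_obs_day, obs_interval = obs_interval,
                 season_total = season_total, count_noise = count_noise,
                 n_traps = as.integer(n_traps), seed = seed),
            class = "trap_gen_config")
}

#' Generate synthetic trap-catch observations for one site-year
#'
#' Accumulates degree-days over `weather` under the true model, evaluates the
#' true emergence curve at each scheduled trap-visit date to get expected
#' cumulative proportions, converts them to interval expectations (the first
#' interval absorbs everything before the first visit; a terminal remainder
#' is folded into the last so expectations sum to 1), draws realized interval
#' counts (multinomial with the seasonal total, or independent Poisson), and
#' splits each interval's count at random across trap ids.
#'
#' Visits run from `first_obs_day` until the true curve passes 99.5% of the
#' season (capped at the end of the weather series).
#'
#' @param weather A [weather_series] covering the biofix onwards.
#' @param config A [trap_gen_config()].
#' @param site_id Site label for the observations.
#' @return A tibble of observations (`site`, `date`, `trap`, `quantity`).
#' @export
generate_trap_catch <- function(weather, config, site_id = "synthetic") {
  stopifnot(inherits(config, "trap_gen_config"))
  acc <- accumulate_degree_days(weather, config$true_params)
  dd10 <- dd_at_proportion(config$true_curve, 0.10)
  if (is.na(date_at_dd(acc, dd10))) {
    stop("true 10% degree-day requirement (", round(dd10),
         ") not reached this season; use a warmer weather config")
  }
  year <- attr(weather, "year")
  offsets <- round(cumsum(rep(config$obs_interval, 200L)))
  jd_obs <- unique(c(config$first_obs_day, config$first_obs_day + offsets))
  dates <- julian_to_date(jd_obs, year)
  dates <- dates[dates <= acc$date[nrow(acc)]]
  D <- dd_at_observation_dates(acc, dates)
  p_true <- ifelse(D > 0, predict_proportion(config$true_curve, pmax(D, 1e-9)), 0)
  last <- match(TRUE, p_true >= 0.995)
  if (!is.na(last)) {
    dates <- dates[seq_len(last)]
    p_true <- p_true[seq_len(last)]
  }
  if (length(dates) < 3L) stop("observation schedule too short for this season")
  # interval expectations; terminal remainder folded into the last interval
  probs <- diff(c(0, p_true))
  probs[length(probs)] <- probs[length(probs)] + (1 - p_true[length(p_true)])
  with_local_seed(config$seed, {
    counts <- if (config$count_noise == "multinomial") {
      as.numeric(stats::rmultinom(1L, size = config$season_total, prob = probs))
    } else {
      stats::rpois(length(probs), lambda = config$season_total * probs)
    }
    traps <- paste0("T", seq_len(config$n_traps))
    split_counts <- vapply(counts, function(ct) {
      as.numeric(stats::rmultinom(1L, size = ct,
                                  prob = rep(1, config$n_traps)))
    }, numeric(config$n_traps))
    tibble::tibble(
      site = site_id,
      date = rep(dates, each = config$n_traps),
      trap = rep(traps, times = length(dates)),
      quantity = as.numeric(split_counts)
    )
  })
}

#' Generate a complete synthetic development/validation study
#'
#' Produces `n_dev + n_val` site-years from a shared data-generating process
#' with site-to-site phenology variation: each site-year perturbs the base
#' weather configuration (annual mean jittered with sd `site_mean_sd` degC,
#' peak day with sd `site_peak_sd` days) and draws its own weather and trap
#' catch. All randomness flows from `seed`. With `dir` supplied, per-site-
#' year weather and trap CSVs plus a YAML study manifest (consumable by
#' [run_pipeline()]) are written.
#'
#' @param n_dev,n_val Numbers of development / validation site-years.
#' @param seed Integer master seed.
#' @param weather_config Base [weather_gen_config()] (its seed is ignored;
#'   the study seed governs).
#' @param true_params Generating [dd_params()].
#' @param true_curve Generating [emergence_curve()].
#' @param season_total,obs_interval,first_obs_day,count_noise Passed to
#'   [trap_gen_config()].
#' @param site_mean_sd,site_peak_sd Between-site-year jitter scales.
#' @param years Calendar years cycled across site-years.
#' @param dir Output directory for CSVs and `manifest.yaml`, or `NULL` to
#'   keep the study in memory only.
#' @return A `synthetic_study` list: `site_years` (each with `site`, `year`,
#'   `role`, `weather`, `observations`, `curve`), `manifest` (tibble),
#'   `true_params`, `true_curve`, `seed`, and `dir`/`manifest_path` when
#'   written.
#' @export
generate_study <- function(n_dev = 6L, n_val = 6L, seed = 1L,
                           weather_config = weather_gen_config(),
                           true_params = dd_params("simple", lower = 15,
                                                   upper = 21.7,
                                                   biofix = "01-01"),
                           true_curve = emergence_curve(slope = 7.41,
                                                        intercept = -43.34),
                           season_total = 10000, obs_interval = 3.5,
                           first_obs_day = 150,
                           count_noise = "multinomial",
                           site_mean_sd = 0.8, site_peak_sd = 4,
                           years = c(2019L, 2020L, 2021L), dir = NULL) {
  stopifnot(n_dev >= 1L, n_val >= 1L)
  n <- n_dev + n_val
  roles <- c(rep("development", n_dev), rep("validation", n_val))
  study <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      site <- sprintf("site%02d", i)
      yr <- years[(i - 1L) %% length(years) + 1L]
      cfg <- weather_config
      cfg$annual_mean <- cfg$annual_mean + stats::rnorm(1L, sd = site_mean_sd)
      cfg$peak_day <- cfg$peak_day + stats::rnorm(1L, sd = site_peak_sd)
      cfg$seed <- NULL  # draw from the study stream
      weather <- generate_weather(cfg, yr, site_id = site)
      tcfg <- trap_gen_config(true_params, true_curve,
                              first_obs_day = first_obs_day,
                              obs_interval = obs_interval,
                              season_total = season_total,
                              count_noise = count_noise, seed = NULL)
      obs <- generate_trap_catch(weather, tcfg, site_id = site)
      list(site = site, year = yr, role = roles[i], weather = weather,
           observations = obs,
           curve = build_curve(obs, site_id = site, year = yr))
    })
  })
  manifest <- tibble::tibble(
    site = vapply(study, `[[`, character(1L), "site"),
    year = vapply(study, `[[`, integer(1L), "year"),
    role = roles,
    weather_csv = sprintf("%s_%d_weather.csv",
                          vapply(study, `[[`, character(1L), "site"),
                          vapply(study, `[[`, integer(1L), "year")),
    trap_csv = sprintf("%s_%d_traps.csv",
                       vapply(study, `[[`, character(1L), "site"),
                       vapply(study, `[[`, integer(1L), "year"))
  )
  out <- structure(list(site_years = study, manifest = manifest,
                        true_params = true_params, true_curve = true_curve,
                        seed = seed),
                   class = "synthetic_study")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      write_weather_csv(study[[i]]$weather,
                        file.path(dir, manifest$weather_csv[i]))
      obs <- study[[i]]$observations
      utils::write.csv(
        data.frame(site = obs$site, date = format(obs$date, "%Y-%m-%d"),
                   trap = obs$trap, quantity = obs$quantity),
        file.path(dir, manifest$trap_csv[i]), row.names = FALSE, quote = FALSE)
    }
    manifest_path <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(list(
      seed = seed,
      site_years = lapply(seq_len(n), function(i) {
        list(site = manifest$site[i], year = manifest$year[i],
             role = manifest$role[i], weather = manifest$weather_csv[i],
             traps = manifest$trap_csv[i])
      })
    ), manifest_path)
    out$dir <- dir
    out$manifest_path <- manifest_path
  }
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  n_dev <- sum(x$manifest$role == "development")
  cat(sprintf("<synthetic_study> %d site-years (%d development, %d validation), seed %s\n",
              nrow(x$manifest), n_dev, nrow(x$manifest) - n_dev,
              format(x$seed)))
  invisible(x)
}

# Convert a synthetic_study (or its subset by role) to the list-of-site-year
# shape consumed by evaluate_candidate/grid_search/validate_model.
#' Extract the model-input site-year list from a synthetic study
#'
#' @param study A [generate_study()] result.
#' @param role `"development"`, `"validation"`, or `"all"`.
#' @return A list of `list(weather = , curve = )` site-year entries.
#' @export
study_site_years <- function(study, role = c("development", "validation",
                                             "all")) {
  role <- match.arg(role)
  keep <- if (role == "all") {
    rep(TRUE, length(study$site_years))
  } else {
    vapply(study$site_years, `[[`, character(1L), "role") == role
  }
  lapply(study$site_years[keep], function(sy) {
    list(weather = sy$weather, curve = sy$curve)
  })
}
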