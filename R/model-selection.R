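#' Degree-day model search grid
#'
#' Defines the exhaustive candidate grid: lower and upper developmental
#' threshold ranges, biofix start dates, and calculation methods. Threshold
#' ranges are specified in degrees Fahrenheit with a whole-degree step — the
#' native resolution of the 0.56 degC (1 degF) increments — and converted to
#' Celsius for computation. The default grid (lower 32-59 degF, upper
#' 68-100 degF, four start dates, two methods) enumerates
#' 28 x 33 x 4 x 2 = 7,392 candidates.
#'
#' @param lower_f Inclusive lower-threshold bounds, degrees Fahrenheit.
#' @param upper_f Inclusive upper-threshold bounds, degrees Fahrenheit.
#' @param step_f Grid step, degrees Fahrenheit.
#' @param start_dates Biofix start dates: `"MM-DD"` strings (calendar mode)
#'   or integer Julian days (literal-Julian mode, e.g. `c(1, 32, 50, 91)`).
#' @param methods Subset of `c("simple", "sine")`.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(lower_f = c(32, 59), upper_f = c(68, 100), step_f = 1,
                      start_dates = c("01-01", "02-01", "03-01", "04-01"),
                      methods = c("simple", "sine")) {
  stopifnot(step_f > 0, length(lower_f) == 2L, length(upper_f) == 2L,
            lower_f[1L] <= lower_f[2L], upper_f[1L] <= upper_f[2L],
            length(start_dates) >= 1L, length(methods) >= 1L)
  methods <- match.arg(methods, c("simple", "sine"), several.ok = TRUE)
  structure(list(lower_f = lower_f, upper_f = upper_f, step_f = step_f,
                 start_dates = start_dates, methods = methods),
            class = "grid_spec")
}

#' Enumerate every candidate in a search grid
#'
#' Cartesian product in deterministic order: method, start date, lower
#' threshold, upper threshold (each ascending in input order). Thresholds are
#' reported in both scales; computation uses Celsius.
#'
#' @param spec A [grid_spec()].
#' @return A tibble with one row per candidate: `method`, `start`,
#'   `lower_f`, `upper_f`, `lower`, `upper` (Celsius).
#' @export
enumerate_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  lows <- seq(spec$lower_f[1L], spec$lower_f[2L], by = spec$step_f)
  ups <- seq(spec$upper_f[1L], spec$upper_f[2L], by = spec$step_f)
  g <- expand.grid(upper_f = ups, lower_f = lows,
                   start = spec$start_dates, method = spec$methods,
                   stringsAsFactors = FALSE)
  g <- g[f_to_c(g$lower_f) < f_to_c(g$upper_f), , drop = FALSE]
  if (nrow(g) == 0L) stop("empty candidate grid")
  tibble::tibble(method = g$method, start = g$start,
                 lower_f = g$lower_f, upper_f = g$upper_f,
                 lower = f_to_c(g$lower_f), upper = f_to_c(g$upper_f))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurement vectors, factored as precision times
#' accuracy:
#' \deqn{CCC = \frac{2\,\mathrm{cov}(x,y)}
#'   {\sigma_x^2 + \sigma_y^2 + (\bar x - \bar y)^2} = r \cdot A}
#' using population (1/n) moments; `r` is the Pearson correlation and the
#' bias-correction factor `A = CCC / r` measures how far the best-fit line
#' deviates from the 45-degree line.
#'
#' @param x,y Numeric vectors of equal length (>= 2) with nonzero variance.
#' @return An `agreement_stats` list: `ccc`, `precision` (r), `accuracy` (A).
#' @examples
#' concordance(1:5, c(1.1, 2.0, 3.2, 3.9, 5.1))
#' @export
concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 paired values")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx == 0 || vy == 0) stop("zero variance in x or y")
  cxy <- mean((x - mx) * (y - my))
  r <- cxy / sqrt(vx * vy)
  ccc <- 2 * cxy / (vx + vy + (mx - my)^2)
  if (r == 0) stop("accuracy undefined when correlation is exactly zero")
  structure(list(ccc = ccc, precision = r, accuracy = ccc / r),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> CCC = %.4f (r = %.4f, A = %.4f)\n",
              x$ccc, x$precision, x$accuracy))
  invisible(x)
}

#' Evaluate one candidate degree-day model on development site-years
#'
#' For a single grid cell: accumulates degree-days per site-year under
#' `params`, maps each trap observation date to its cumulative degree-days,
#' pools all (degree-day, cumulative proportion) points across site-years,
#' fits the log-logistic emergence curve, inverts it at `target_p` to get the
#' degree-day requirement, predicts the target date per site-year from its
#' own accumulation, and scores predicted vs observed dates with Lin's CCC.
#'
#' Site-years whose season never reaches the fitted degree-day requirement
#' are excluded with a warning; a candidate with fewer than two usable
#' site-years is returned unscorable (`agreement = NULL`) and ranks last.
#'
#' @param dev_data A list of site-years, each a list with elements `weather`
#'   (a [weather_series]) and `curve` (a [build_curve()] result).
#' @param params A [dd_params()].
#' @param target_p Target proportion scored (default 0.10).
#' @return A `candidate_result` list: `params`, `fit`, `dd_target`,
#'   `predicted`, `observed` (named Julian days), `agreement`, `scorable`,
#'   `excluded` (site-year labels dropped).
#' @export
evaluate_candidate <- function(dev_data, params, target_p = 0.10) {
  stopifnot(inherits(params, "dd_params"), length(dev_data) >= 1L)
  labels <- vapply(dev_data, function(sy) {
    paste0(attr(sy$curve, "site_id"), "_", attr(sy$curve, "year"))
  }, character(1L))
  accs <- lapply(dev_data, function(sy) {
    accumulate_degree_days(sy$weather, params)
  })
  pts_D <- list(); pts_y <- list(); pts_g <- list()
  for (j in seq_along(dev_data)) {
    crv <- dev_data[[j]]$curve
    Dj <- dd_at_observation_dates(accs[[j]], crv$date)
    keep <- Dj > 0
    pts_D[[j]] <- Dj[keep]
    pts_y[[j]] <- crv$cumulative_proportion[keep]
    pts_g[[j]] <- rep(labels[j], sum(keep))
  }
  fit <- fit_log_logistic(unlist(pts_D), unlist(pts_y))
  dd_target <- dd_at_proportion(fit$curve, target_p)
  predicted <- vapply(accs, date_at_dd, numeric(1L), target = dd_target)
  observed <- vapply(dev_data, function(sy) {
    observed_date_at_proportion(sy$curve, target_p)
  }, numeric(1L))
  names(predicted) <- names(observed) <- labels
  usable <- !is.na(predicted)
  if (any(!usable)) {
    warning("degree-day requirement not reached in: ",
            paste(labels[!usable], collapse = ", "))
  }
  scorable <- sum(usable) >= 2L
  agreement <- if (scorable) {
    concordance(predicted[usable], observed[usable])
  } else {
    NULL
  }
  structure(list(params = params, fit = fit, dd_target = dd_target,
                 target_p = target_p,
                 predicted = predicted[usable], observed = observed[usable],
                 agreement = agreement, scorable = scorable,
                 excluded = labels[!usable],
                 points = tibble::tibble(group = unlist(pts_g),
                                         D = unlist(pts_D),
                                         y = unlist(pts_y))),
            class = "candidate_result")
}

#' @export
print.candidate_result <- function(x, ...) {
  cat(sprintf("<candidate_result> %s %.2f/%.2f degC, biofix %s\n",
              x$params$method, x$params$lower, x$params$upper,
              if (is.numeric(x$params$biofix)) paste("Julian", x$params$biofix)
              else x$params$biofix))
  cat(sprintf("  DD at p = %.2f: %.1f | AIC = %.3f | %s\n", x$target_p,
              x$dd_target, x$fit$aic,
              if (x$scorable) sprintf("CCC = %.4f", x$agreement$ccc)
              else "unscorable"))
  invisible(x)
}

#' Rank candidates and select the optimum
#'
#' Stable sort by CCC descending, then AIC ascending, then original
#' enumeration order; unscorable candidates rank below all scorable ones.
#' Also reports where the selected candidate falls when candidates are
#' ordered by AIC alone — the measure of fit across the whole emergence
#' distribution, as opposed to agreement at the target percentile.
#'
#' @param candidates A list of `candidate_result` objects, or the candidate
#'   tibble produced by [grid_search()].
#' @return A `selection_report` list: `ranking` (tibble, ranked), `selected`
#'   (index into the original candidate order), `aic_rank_of_selected`.
#' @export
rank_and_select <- function(candidates) {
  tab <- if (inherits(candidates, "data.frame")) {
    candidates
  } else {
    tibble::tibble(
      method = vapply(candidates, function(c) c$params$method, character(1L)),
      start = vapply(candidates, function(c) as.character(c$params$biofix),
                     character(1L)),
      lower = vapply(candidates, function(c) c$params$lower, numeric(1L)),
      upper = vapply(candidates, function(c) c$params$upper, numeric(1L)),
      aic = vapply(candidates, function(c) c$fit$aic, numeric(1L)),
      ccc = vapply(candidates, function(c) {
        if (c$scorable) c$agreement$ccc else NA_real_
      }, numeric(1L)),
      dd_target = vapply(candidates, function(c) c$dd_target, numeric(1L))
    )
  }
  if (!nrow(tab)) stop("no candidates")
  if (all(is.na(tab$ccc))) stop("no scorable candidates")
  tab$candidate <- seq_len(nrow(tab))
  ord <- order(-tab$ccc, tab$aic, tab$candidate, na.last = TRUE)
  ranked <- tab[ord, , drop = FALSE]
  selected <- ranked$candidate[1L]
  aic_rank <- rank(tab$aic, ties.method = "first")[selected]
  structure(list(ranking = tibble::as_tibble(ranked), selected = selected,
                 aic_rank_of_selected = as.integer(aic_rank),
                 n_candidates = nrow(tab)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  top <- x$ranking[1L, ]
  cat(sprintf("<selection_report> %d candidates; selected #%d: %s %.2f/%.2f degC, start %s\n",
              x$n_candidates, x$selected, top$method, top$lower, top$upper,
              as.character(top$start)))
  cat(sprintf("  CCC = %.4f, AIC = %.3f (AIC-alone rank %d of %d)\n",
              top$ccc, top$aic, x$aic_rank_of_selected, x$n_candidates))
  invisible(x)
}

#' Exhaustive grid search for the optimum degree-day model
#'
#' Evaluates every candidate of `spec` on the development site-years via
#' [evaluate_candidate()] semantics, ranks by CCC (descending) with AIC
#' tie-breaking, and returns the ranked table together with the fully
#' evaluated selected candidate. Daily degree-day vectors are shared across
#' start dates of the same method/threshold cell, so results are identical
#' to, but faster than, independent per-candidate evaluation.
#'
#' @inheritParams evaluate_candidate
#' @param spec A [grid_spec()].
#' @param verbose Log progress to stderr.
#' @return A `selection_report` (see [rank_and_select()]) with two extra
#'   elements: `candidates` (the unranked candidate tibble in enumeration
#'   order) and `selected_result` (the [evaluate_candidate()] output of the
#'   winning candidate).
#' @export
grid_search <- function(dev_data, spec = grid_spec(), target_p = 0.10,
                        verbose = FALSE) {
  grid <- enumerate_grid(spec)
  n <- nrow(grid)
  if (verbose) message("grid search over ", n, " candidates, ",
                       length(dev_data), " site-years")
  # pre-extract per-site-year vectors once
  years <- vapply(dev_data, function(sy) attr(sy$weather, "year"), integer(1L))
  obs_dates <- lapply(dev_data, function(sy) sy$curve$date)
  obs_y <- lapply(dev_data, function(sy) sy$curve$cumulative_proportion)
  obs_10 <- vapply(dev_data, function(sy) {
    observed_date_at_proportion(sy$curve, target_p)
  }, numeric(1L))

  aic <- ccc <- ddt <- slope <- intercept <- rep(NA_real_, n)
  scorable <- rep(FALSE, n)

  # iterate threshold/method cells; reuse daily dd across start dates
  cells <- unique(grid[, c("method", "lower", "upper")])
  t0 <- Sys.time()
  for (ci in seq_len(nrow(cells))) {
    method <- cells$method[ci]; lo <- cells$lower[ci]; up <- cells$upper[ci]
    daily <- lapply(dev_data, function(sy) {
      w <- sy$weather
      if (method == "simple") {
        simple_daily_dd(w$tmin, w$tmax, lo, up)
      } else {
        sine_daily_dd(w$tmin, w$tmax, c(w$tmin[-1L], NA_real_), lo, up)
      }
    })
    rows <- which(grid$method == method & grid$lower == lo & grid$upper == up)
    for (ri in rows) {
      start <- grid$start[ri]
      D_all <- vector("list", length(dev_data))
      cums <- vector("list", length(dev_data))
      jd0 <- integer(length(dev_data))
      ok <- TRUE
      for (j in seq_along(dev_data)) {
        w <- dev_data[[j]]$weather
        sd_j <- resolve_start_date(start, years[j])
        if (w$date[1L] > sd_j) { ok <- FALSE; break }
        keep <- w$date >= sd_j
        cum <- cumsum(daily[[j]][keep])
        cums[[j]] <- cum
        jd0[j] <- julian_day(w$date[keep][1L])
        idx <- match(obs_dates[[j]], w$date[keep])
        if (anyNA(idx)) { ok <- FALSE; break }
        D_all[[j]] <- cum[idx]
      }
      if (!ok) next
      D <- unlist(D_all); y <- unlist(obs_y)
      pos <- D > 0
      fit <- tryCatch(fit_log_logistic(D[pos], y[pos]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      aic[ri] <- fit$aic
      slope[ri] <- fit$curve$slope
      intercept[ri] <- fit$curve$intercept
      dd10 <- dd_at_proportion(fit$curve, target_p)
      ddt[ri] <- dd10
      pred <- vapply(seq_along(dev_data), function(j) {
        cum <- cums[[j]]
        k <- match(TRUE, cum >= dd10)
        if (is.na(k)) return(NA_real_)
        prev <- if (k == 1L) 0 else cum[k - 1L]
        inc <- cum[k] - prev
        (jd0[j] + k - 1L) - 1 + (dd10 - prev) / inc
      }, numeric(1L))
      use <- !is.na(pred)
      if (sum(use) >= 2L) {
        ag <- tryCatch(concordance(pred[use], obs_10[use]),
                       error = function(e) NULL)
        if (!is.null(ag)) {
          ccc[ri] <- ag$ccc
          scorable[ri] <- TRUE
        }
      }
    }
    if (verbose && ci %% 200L == 0L) {
      message(sprintf("  ... %d/%d cells (%.1f s)", ci, nrow(cells),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  tab <- tibble::tibble(method = grid$method, start = grid$start,
                        lower_f = grid$lower_f, upper_f = grid$upper_f,
                        lower = grid$lower, upper = grid$upper,
                        slope = slope, intercept = intercept,
                        dd_target = ddt, aic = aic, ccc = ccc)
  report <- rank_and_select(tab[, c("method", "start", "lower", "upper",
                                    "aic", "ccc", "dd_target")])
  sel <- report$selected
  sel_params <- dd_params(grid$method[sel], lower = grid$lower[sel],
                          upper = grid$upper[sel],
                          biofix = if (is.character(grid$start[sel])) {
                            grid$start[sel]
                          } else {
                            as.numeric(grid$start[sel])
                          })
  selected_result <- evaluate_candidate(dev_data, sel_params,
                                        target_p = target_p)
  report$candidates <- tab
  report$selected_result <- selected_result
  if (verbose) {
    message(sprintf("done in %.1f s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  report
}
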