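#' Log-logistic emergence curve
#'
#' The emergence model relates the cumulative proportion of seasonal
#' trap-catch `p` to accumulated degree-days `D` through a logistic function
#' of `ln(D)`:
#'
#' \deqn{p(D) = \frac{e^{s \ln D + i}}{1 + e^{s \ln D + i}}}
#'
#' with slope `s` (dimensionless, on the log-degree-day scale) and intercept
#' `i`. A positive slope gives a curve increasing in `D`.
#'
#' @param slope Slope `s` on the `ln(D)` scale.
#' @param intercept Intercept `i`.
#' @return An `emergence_curve` object.
#' @examples
#' crv <- emergence_curve(slope = 7.41, intercept = -43.34)
#' predict_proportion(crv, 257)
#' dd_at_proportion(crv, 0.5)
#' @export
emergence_curve <- function(slope, intercept) {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            length(slope) == 1L, length(intercept) == 1L,
            is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept),
            class = "emergence_curve")
}

#' @export
print.emergence_curve <- function(x, ...) {
  cat(sprintf("<emergence_curve> p(D) = plogis(%.4f * ln D + %.4f)\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Predicted cumulative trap-catch proportion at a degree-day total
#'
#' Evaluates the log-logistic emergence curve; numerically stable for large
#' `|s * ln D + i|` via `plogis()`.
#'
#' @param curve An [emergence_curve()].
#' @param D Accumulated degree-days, strictly positive. Vectorised.
#' @return Proportions in (0, 1).
#' @export
predict_proportion <- function(curve, D) {
  stopifnot(inherits(curve, "emergence_curve"))
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("degree-days must be strictly positive")
  }
  stats::plogis(curve$slope * log(D) + curve$intercept)
}

#' Degree-days at a target cumulative proportion
#'
#' Exact inverse of [predict_proportion()]:
#' `D = exp((logit(p) - i) / s)`.
#'
#' @param curve An [emergence_curve()].
#' @param p Proportions in (0, 1). Vectorised.
#' @return Degree-day totals.
#' @export
dd_at_proportion <- function(curve, p) {
  stopifnot(inherits(curve, "emergence_curve"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must be strictly between 0 and 1")
  }
  if (curve$slope == 0) stop("curve with zero slope is not invertible")
  exp((stats::qlogis(p) - curve$intercept) / curve$slope)
}

#' Degree-day requirements at standard trap-catch percentiles
#'
#' Convenience wrapper inverting the emergence curve at a set of proportions,
#' reported in degree-Celsius and degree-Fahrenheit days (F = C * 9/5 for a
#' degree-day quantity).
#'
#' @param curve An [emergence_curve()].
#' @param probs Proportions; default the 10/25/50/75/90% forecast set.
#' @return A tibble with columns `proportion`, `dd_c`, `dd_f`.
#' @export
dd_percentiles <- function(curve, probs = c(0.10, 0.25, 0.50, 0.75, 0.90)) {
  dd_c <- dd_at_proportion(curve, probs)
  tibble::tibble(proportion = probs, dd_c = dd_c, dd_f = dd_c * 9 / 5)
}

# Bernoulli-form log-likelihood of fractional responses y under fitted
# probabilities p; y of exactly 0 or 1 contribute only their defined term.
bernoulli_loglik <- function(y, p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Residual (saturated-model-relative) deviance for fractional responses:
# 2 * sum[y ln(y/p) + (1-y) ln((1-y)/(1-p))], with 0 * ln 0 = 0. This is the
# quantity whose scaled differences behave like a chi-square; the plain
# -2 * loglik carries the intrinsic Bernoulli entropy and would wreck the
# dispersion estimate in F tests.
residual_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  t1 <- ifelse(y > 0, y * log(y / p), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - p)), 0)
  2 * sum(t1 + t2)
}

# IRLS for a logistic model with arbitrary design matrix X and fractional
# responses y in [0, 1], unit weights. Falls back to BFGS on the negative
# log-likelihood if IRLS fails to converge. Returns coefficients and the
# maximised log-likelihood.
fit_logistic_design <- function(X, y, max_iter = 100L, tol = 1e-10) {
  stopifnot(nrow(X) == length(y), all(y >= 0), all(y <= 1))
  # deterministic initialisation: least squares on empirical logits,
  # responses clamped to [0.005, 0.995] for initialisation only
  z0 <- stats::qlogis(pmin(pmax(y, 0.005), 0.995))
  beta <- tryCatch(qr.coef(qr(X), z0), error = function(e) rep(0, ncol(X)))
  beta[is.na(beta)] <- 0
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    beta <- fit$coefficients
    dev <- -2 * bernoulli_loglik(y, stats::plogis(drop(X %*% beta)))
    if (is.finite(dev) && abs(dev - dev_old) < tol) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  if (!converged) {
    nll <- function(b) -bernoulli_loglik(y, stats::plogis(drop(X %*% b)))
    opt <- stats::optim(beta, nll, method = "BFGS",
                        control = list(maxit = 500L, reltol = 1e-14))
    if (!is.finite(opt$value)) {
      stop("logistic fit failed to converge (final deviance ",
           format(dev_old), " after ", iter, " IRLS iterations)")
    }
    # accept whichever of the two candidates has the higher likelihood
    if (opt$value < dev_old / 2) beta <- opt$par
    converged <- TRUE
  }
  ll <- bernoulli_loglik(y, stats::plogis(drop(X %*% beta)))
  list(coefficients = beta, log_likelihood = ll, iterations = iter,
       converged = converged)
}

#' Fit the log-logistic emergence curve by maximum likelihood
#'
#' Maximises the unit-weight Bernoulli-form log-likelihood
#' `sum(y * ln p + (1 - y) * ln(1 - p))` over the slope and intercept of the
#' emergence curve, where each observation is one (degree-day, cumulative
#' proportion) pair — i.e. a binomial-family generalized linear fit of the
#' cumulative proportion on natural-log degree-days with one unit-weight row
#' per observation date. With `weights` supplied (e.g. interval beetle
#' counts) a count-weighted fit is performed instead.
#'
#' Fitting is by iteratively reweighted least squares with deterministic
#' initialisation from the least-squares line of empirical logits, converging
#' at an absolute deviance change below 1e-10 (at most 100 iterations), with
#' a BFGS fall-back. Proportions of exactly 0 or 1 are retained; their
#' likelihood terms use the defined limits.
#'
#' @param D Accumulated degree-days (> 0).
#' @param y Cumulative trap-catch proportions in `[0, 1]`.
#' @param weights Optional non-negative observation weights (default unit).
#' @return A `phenodd_fit` object: `curve` ([emergence_curve()]), `n_obs`,
#'   `log_likelihood`, `deviance` (`-2 * log_likelihood`), `aic`
#'   (`2 * 2 - 2 * log_likelihood`), `residual_df`, `converged`,
#'   `iterations`.
#' @export
fit_log_logistic <- function(D, y, weights = NULL) {
  if (length(D) != length(y)) stop("D and y must have equal length")
  if (length(D) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("degree-days must be strictly positive")
  }
  if (any(y < 0) || any(y > 1)) stop("proportions must lie in [0, 1]")
  if (length(unique(y)) == 1L) stop("responses are all identical; curve not estimable")
  X <- cbind(intercept = 1, log_dd = log(D))
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("weights must be non-negative")
    # count-weighted likelihood: replicate the unit-weight machinery by
    # scaling rows; equivalent to weighted Bernoulli log-likelihood
    res <- fit_logistic_weighted(X, y, weights)
  } else {
    res <- fit_logistic_design(X, y)
  }
  ll <- res$log_likelihood
  k <- 2L
  structure(list(
    curve = emergence_curve(slope = unname(res$coefficients[2L]),
                            intercept = unname(res$coefficients[1L])),
    n_obs = length(y),
    log_likelihood = ll,
    deviance = -2 * ll,
    aic = 2 * k - 2 * ll,
    residual_df = length(y) - k,
    converged = res$converged,
    iterations = res$iterations
  ), class = "phenodd_fit")
}

# Count-weighted variant used behind the `weights` flag of fit_log_logistic.
fit_logistic_weighted <- function(X, y, w) {
  nll <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    -sum(w * (y * log(p) + (1 - y) * log(1 - p)))
  }
  z0 <- stats::qlogis(pmin(pmax(y, 0.005), 0.995))
  b0 <- tryCatch(qr.coef(qr(X * sqrt(w)), z0 * sqrt(w)),
                 error = function(e) rep(0, ncol(X)))
  b0[is.na(b0)] <- 0
  opt <- stats::optim(b0, nll, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-14))
  list(coefficients = opt$par, log_likelihood = -opt$value,
       iterations = opt$counts[["function"]],
       converged = opt$convergence == 0L)
}

#' @export
print.phenodd_fit <- function(x, ...) {
  cat(sprintf(
    "<phenodd_fit> slope %.4f, intercept %.4f | n = %d, AIC = %.3f\n",
    x$curve$slope, x$curve$intercept, x$n_obs, x$aic))
  invisible(x)
}

#' Test for site-year differences in the emergence curve
#'
#' Compares the pooled emergence fit against a model with site-year-specific
#' intercepts (`which = "intercept"`) or site-year-specific slopes on the
#' log-degree-day effect (`which = "slope"`), via the deviance-based F
#' statistic
#' `F = ((dev_reduced - dev_full) / df_diff) / (dev_full / df_full)`,
#' with `df_full = n - k_full`, referred to an F distribution. A large p
#' indicates the pooled curve describes all site-years equally well.
#'
#' Deviances entering F are residual (saturated-model-relative) deviances,
#' so the denominator estimates the dispersion; the numerator difference is
#' the same under either deviance convention because the saturated term
#' cancels.
#'
#' @param D Accumulated degree-days (> 0).
#' @param y Cumulative trap-catch proportions in `[0, 1]`.
#' @param group Site-year labels, one per observation (>= 2 distinct values,
#'   each with >= 2 observations).
#' @param which Add the group effect to the `"intercept"` or to the
#'   degree-day `"slope"`.
#' @return A list: `f_statistic`, `df_numerator`, `df_denominator`,
#'   `p_value`, plus both fits' deviances.
#' @export
site_year_covariate_test <- function(D, y, group,
                                     which = c("intercept", "slope")) {
  which <- match.arg(which)
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 site-year groups")
  if (any(table(group) < 2L)) {
    stop("every site-year group needs at least 2 observations")
  }
  if (any(D <= 0)) stop("degree-days must be strictly positive")
  logD <- log(D)
  X_red <- cbind(1, logD)
  G <- stats::model.matrix(~ group)[, -1L, drop = FALSE]
  X_full <- if (which == "intercept") {
    cbind(1, logD, G)
  } else {
    cbind(1, logD, G * logD)
  }
  if (qr(X_full)$rank < ncol(X_full)) {
    stop("full model design is singular; groups not estimable")
  }
  red <- fit_logistic_design(X_red, y)
  full <- fit_logistic_design(X_full, y)
  dev_red <- residual_deviance(y, stats::plogis(drop(X_red %*% red$coefficients)))
  dev_full <- residual_deviance(y, stats::plogis(drop(X_full %*% full$coefficients)))
  df_num <- ncol(X_full) - ncol(X_red)
  df_den <- length(y) - ncol(X_full)
  f <- max(0, (dev_red - dev_full) / df_num) / (dev_full / df_den)
  list(f_statistic = f, df_numerator = df_num, df_denominator = df_den,
       p_value = stats::pf(f, df_num, df_den, lower.tail = FALSE),
       deviance_reduced = dev_red, deviance_full = dev_full)
}
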