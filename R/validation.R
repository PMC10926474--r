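#' Validate a selected degree-day model on hold-out site-years
#'
#' Applies the selected candidate's fitted emergence curve to independent
#' site-years: the predicted target date per site-year is the date at which
#' its own degree-day accumulation reaches the fitted degree-day requirement;
#' the observed date comes from its trap-catch curve. Errors are reported as
#' predicted minus observed (negative means the model runs early), with the
#' sample (n - 1) standard deviation, and agreement by Lin's CCC.
#'
#' @param selected A `candidate_result` from [evaluate_candidate()] or
#'   [grid_search()]`$selected_result`.
#' @param holdout A list of site-years, each a list with `weather` and
#'   `curve` elements (same shape as the development data).
#' @param p Target proportion (default 0.10).
#' @return A `validation_stats` list: `per_site_year` tibble (site, year,
#'   predicted, observed, error in days), `mean_error`, `std_dev`,
#'   `min_error`, `max_error`, `agreement`, `excluded`.
#' @export
validate_model <- function(selected, holdout, p = 0.10) {
  stopifnot(inherits(selected, "candidate_result"), length(holdout) >= 1L)
  dd_req <- dd_at_proportion(selected$fit$curve, p)
  site <- vapply(holdout, function(sy) attr(sy$curve, "site_id"), character(1L))
  year <- vapply(holdout, function(sy) attr(sy$curve, "year"), integer(1L))
  predicted <- vapply(holdout, function(sy) {
    acc <- accumulate_degree_days(sy$weather, selected$params)
    date_at_dd(acc, dd_req)
  }, numeric(1L))
  observed <- vapply(holdout, function(sy) {
    observed_date_at_proportion(sy$curve, p)
  }, numeric(1L))
  usable <- !is.na(predicted)
  if (any(!usable)) {
    warning("degree-day requirement not reached in: ",
            paste(paste0(site[!usable], "_", year[!usable]), collapse = ", "))
  }
  per <- tibble::tibble(site = site[usable], year = year[usable],
                        predicted = predicted[usable],
                        observed = observed[usable],
                        error = predicted[usable] - observed[usable])
  agreement <- if (nrow(per) >= 2L) {
    concordance(per$predicted, per$observed)
  } else {
    NULL
  }
  structure(list(per_site_year = per,
                 mean_error = mean(per$error),
                 std_dev = stats::sd(per$error),
                 min_error = min(per$error),
                 max_error = max(per$error),
                 agreement = agreement,
                 target_p = p,
                 dd_requirement = dd_req,
                 excluded = paste0(site[!usable], "_", year[!usable])),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf("<validation_stats> %d site-years at p = %.2f (DD requirement %.1f)\n",
              nrow(x$per_site_year), x$target_p, x$dd_requirement))
  cat(sprintf("  mean error %.2f d (sd %.3f, range %.2f to %.2f)\n",
              x$mean_error, x$std_dev, x$min_error, x$max_error))
  if (!is.null(x$agreement)) {
    cat(sprintf("  CCC = %.4f (r = %.4f, A = %.4f)\n", x$agreement$ccc,
                x$agreement$precision, x$agreement$accuracy))
  }
  invisible(x)
}
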