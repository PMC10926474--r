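#' Read a YAML study manifest
#'
#' A manifest lists site-year entries (`site`, `year`, `role` in
#' development/validation, `weather` CSV path, `traps` CSV path), with paths
#' relative to the manifest's directory. [generate_study()] writes this
#' format.
#'
#' @param path Path to `manifest.yaml`.
#' @return A list with `entries` (tibble) and `base_dir`.
#' @export
read_study_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  if (is.null(m$site_years) || length(m$site_years) == 0L) {
    stop("manifest has no site_years entries")
  }
  entries <- tibble::tibble(
    site = vapply(m$site_years, function(e) as.character(e$site), character(1L)),
    year = vapply(m$site_years, function(e) as.integer(e$year), integer(1L)),
    role = vapply(m$site_years, function(e) as.character(e$role), character(1L)),
    weather = vapply(m$site_years, function(e) as.character(e$weather), character(1L)),
    traps = vapply(m$site_years, function(e) as.character(e$traps), character(1L))
  )
  if (!any(entries$role == "development")) {
    stop("manifest needs at least one development site-year")
  }
  list(entries = entries, base_dir = dirname(path), seed = m$seed)
}

# Load the site-year list (weather series + trap curve) for one manifest role.
load_site_years <- function(manifest, role) {
  e <- manifest$entries[manifest$entries$role == role, , drop = FALSE]
  lapply(seq_len(nrow(e)), function(i) {
    wpath <- file.path(manifest$base_dir, e$weather[i])
    tpath <- file.path(manifest$base_dir, e$traps[i])
    if (!file.exists(wpath)) stop("weather file not found: ", wpath)
    if (!file.exists(tpath)) stop("trap file not found: ", tpath)
    weather <- read_weather_csv(wpath, site_id = e$site[i])
    obs <- read_trap_csv(tpath)
    list(weather = weather,
         curve = build_curve(obs, site_id = e$site[i], year = e$year[i]))
  })
}

#' Run the full model-development pipeline on a study manifest
#'
#' Executes the complete analysis: builds cumulative trap-catch curves, runs
#' the exhaustive grid search on the development site-years, validates the
#' selected model on the validation site-years (if any), and writes four
#' artifacts to `out_dir`:
#'
#' * `ranked_candidates.csv` — every grid cell with thresholds (degC), method,
#'   start, AIC and CCC, ranked by CCC then AIC (degree-days to 1 decimal);
#' * `selection.json` — the selected model, its coefficients, agreement
#'   statistics and AIC-alone rank;
#' * `validation.csv` — per-site-year predicted/observed target dates and the
#'   summary error statistics;
#' * `percentile_table.csv` — degree-day requirements at 10/25/50/75/90%
#'   trap-catch in degC and degF (F = C * 9/5), rounded to integers.
#'
#' @param manifest Path to a `manifest.yaml` or the result of
#'   [read_study_manifest()].
#' @param out_dir Output directory for artifacts.
#' @param spec A [grid_spec()]; default is the full 7,392-candidate grid.
#' @param target_p Target trap-catch proportion (default 0.10).
#' @param verbose Log stage progress and timing to stderr.
#' @return Invisibly, a list with `selection` (the grid-search report),
#'   `validation` (a `validation_stats` or `NULL`), `percentiles` (tibble),
#'   and `artifacts` (named file paths).
#' @export
run_pipeline <- function(manifest, out_dir, spec = grid_spec(),
                         target_p = 0.10, verbose = TRUE) {
  if (is.character(manifest)) manifest <- read_study_manifest(manifest)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  say("loading site-years ...")
  dev <- load_site_years(manifest, "development")
  val_entries <- manifest$entries[manifest$entries$role == "validation", ]
  val <- if (nrow(val_entries)) load_site_years(manifest, "validation") else NULL
  say(sprintf("  %d development, %d validation site-years", length(dev),
              if (is.null(val)) 0L else length(val)))

  t0 <- Sys.time()
  report <- grid_search(dev, spec = spec, target_p = target_p,
                        verbose = verbose)
  say(sprintf("grid search: %d candidates in %.1f s", report$n_candidates,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  ranked_path <- file.path(out_dir, "ranked_candidates.csv")
  rk <- report$ranking
  rk_out <- data.frame(rank = seq_len(nrow(rk)),
                       lower_c = round(rk$lower, 1),
                       upper_c = round(rk$upper, 1),
                       method = rk$method, start = as.character(rk$start),
                       aic = round(rk$aic, 3), ccc = round(rk$ccc, 4),
                       dd_target = round(rk$dd_target, 1))
  utils::write.csv(rk_out, ranked_path, row.names = FALSE, quote = FALSE)

  sel <- report$selected_result
  percentiles <- dd_percentiles(sel$fit$curve)
  pct_path <- file.path(out_dir, "percentile_table.csv")
  utils::write.csv(
    data.frame(proportion = percentiles$proportion,
               dd_c = round(percentiles$dd_c),
               dd_f = round(percentiles$dd_f)),
    pct_path, row.names = FALSE, quote = FALSE)

  sel_path <- file.path(out_dir, "selection.json")
  jsonlite::write_json(list(
    seed = manifest$seed,
    method = sel$params$method,
    lower_c = sel$params$lower, upper_c = sel$params$upper,
    biofix = as.character(sel$params$biofix),
    slope = sel$fit$curve$slope, intercept = sel$fit$curve$intercept,
    aic = sel$fit$aic, n_obs = sel$fit$n_obs,
    dd_target = sel$dd_target, target_p = target_p,
    ccc = sel$agreement$ccc, precision = sel$agreement$precision,
    accuracy = sel$agreement$accuracy,
    aic_rank_of_selected = report$aic_rank_of_selected,
    n_candidates = report$n_candidates
  ), sel_path, auto_unbox = TRUE, digits = NA)

  validation <- NULL
  val_path <- NULL
  if (!is.null(val)) {
    validation <- validate_model(sel, val, p = target_p)
    val_path <- file.path(out_dir, "validation.csv")
    per <- validation$per_site_year
    utils::write.csv(
      data.frame(site = per$site, year = per$year,
                 predicted_jd = round(per$predicted, 2),
                 observed_jd = round(per$observed, 2),
                 error_days = round(per$error, 2)),
      val_path, row.names = FALSE, quote = FALSE)
    say(sprintf("validation: mean error %.2f d, CCC %.4f",
                validation$mean_error,
                if (is.null(validation$agreement)) NA_real_
                else validation$agreement$ccc))
  }

  artifacts <- c(ranked_candidates = ranked_path, selection = sel_path,
                 percentile_table = pct_path,
                 if (!is.null(val_path)) c(validation = val_path))
  invisible(list(selection = report, validation = validation,
                 percentiles = percentiles, artifacts = artifacts))
}
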