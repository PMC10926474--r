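test_that("concordance satisfies Lin's algebraic identities", {
  set.seed(2)
  x <- rnorm(25, 180, 6)
  expect_equal(concordance(x, x)$ccc, 1)
  expect_equal(concordance(x, x)$precision, 1)
  expect_equal(concordance(x, x)$accuracy, 1)

  # location shift keeps r = 1 but drops CCC below 1
  sh <- concordance(x, x + 3)
  expect_equal(sh$precision, 1)
  expect_lt(sh$ccc, 1)

  for (i in 1:25) {
    a <- rnorm(12); b <- rnorm(12, 1, 2)
    st <- concordance(a, b)
    expect_equal(st$ccc, st$precision * st$accuracy, tolerance = 1e-12)
    expect_lte(abs(st$ccc), abs(st$precision) + 1e-12)
    expect_lte(abs(st$precision), 1 + 1e-12)
    expect_gt(st$accuracy, 0)
    expect_lte(st$accuracy, 1 + 1e-12)
    # symmetry and the independently coded defining-formula oracle
    expect_equal(st$ccc, concordance(b, a)$ccc)
    expect_equal(st$ccc, oracle_ccc(a, b))
  }

  expect_error(concordance(1:3, 1:4), "equal length")
  expect_error(concordance(1, 2), "at least 2")
  expect_error(concordance(c(1, 1), c(1, 2)), "zero variance")
})

test_that("the default grid enumerates 7,392 candidates in contract order", {
  grid <- enumerate_grid(grid_spec())
  expect_equal(nrow(grid), 7392L)
  expect_equal(length(unique(grid$lower_f)), 28L)
  expect_equal(length(unique(grid$upper_f)), 33L)
  expect_equal(unique(grid$method), c("simple", "sine"))
  # thresholds in whole-degree-F steps converted to Celsius
  expect_equal(sort(unique(grid$lower)), f_to_c(32:59))
  expect_true(all(grid$lower < grid$upper))

  single <- enumerate_grid(grid_spec(lower_f = c(59, 59), upper_f = c(71, 71),
                                     start_dates = "01-01",
                                     methods = "simple"))
  expect_equal(nrow(single), 1L)
  expect_equal(single$lower, 15)

  # 2 x 2 x 1 x 1: method, start, lower, upper nesting order
  g4 <- enumerate_grid(grid_spec(lower_f = c(50, 51), upper_f = c(70, 71),
                                 start_dates = "01-01", methods = "simple"))
  expect_equal(nrow(g4), 4L)
  expect_equal(g4$lower_f, c(50, 50, 51, 51))
  expect_equal(g4$upper_f, c(70, 71, 70, 71))
})

# A small zero-weather-noise study shared by the selection tests: site-to-site
# variation comes only from the jittered seasonal cycle, so predicted and
# observed dates should agree almost perfectly at the true parameters.
quiet_study <- generate_study(
  n_dev = 6, n_val = 2, seed = 99,
  weather_config = weather_gen_config(noise_sd = 0),
  season_total = 50000
)
quiet_dev <- study_site_years(quiet_study, "development")

test_that("the true candidate scores near-perfect agreement on clean data", {
  cand <- evaluate_candidate(quiet_dev, quiet_study$true_params)
  expect_true(cand$scorable)
  expect_gte(cand$agreement$ccc, 0.999)
  expect_equal(cand$agreement$ccc,
               cand$agreement$precision * cand$agreement$accuracy,
               tolerance = 1e-12)
  expect_lt(max(abs(cand$predicted - cand$observed)), 2)

  # grossly wrong thresholds score strictly worse
  wrong <- evaluate_candidate(
    quiet_dev, dd_params("simple", lower = 0, upper = 37, biofix = "01-01"))
  expect_lt(wrong$agreement$ccc, cand$agreement$ccc)
})

test_that("candidate evaluation is invariant to site-year order", {
  cand <- evaluate_candidate(quiet_dev, quiet_study$true_params)
  perm <- evaluate_candidate(quiet_dev[c(4, 1, 6, 2, 5, 3)],
                             quiet_study$true_params)
  expect_equal(perm$fit$curve, cand$fit$curve)
  expect_equal(perm$dd_target, cand$dd_target)
  expect_equal(perm$agreement$ccc, cand$agreement$ccc)
  expect_equal(perm$predicted[names(cand$predicted)], cand$predicted)
  expect_equal(perm$observed[names(cand$observed)], cand$observed)
})

test_that("ranking selects highest CCC with AIC as tie-break, deterministically", {
  tab <- tibble::tibble(
    method = c("simple", "simple", "sine"),
    start = "01-01",
    lower = c(15, 15, 11.7), upper = c(21.7, 22.2, 34.4),
    aic = c(47.1, 46.2, 51.3),
    ccc = c(0.899, 0.899, 0.895),
    dd_target = c(257, 255, 240)
  )
  rep1 <- rank_and_select(tab)
  expect_equal(rep1$selected, 2L)  # equal CCC, lower AIC wins
  expect_equal(rep1$ranking$aic[1], 46.2)
  expect_equal(rep1$aic_rank_of_selected, 1L)

  shuffled <- rank_and_select(tab[c(3, 1, 2), ])
  expect_equal(shuffled$ranking$aic[1], 46.2)
  expect_equal(shuffled$ranking$ccc, rep1$ranking$ccc)

  one <- rank_and_select(tab[1, ])
  expect_equal(one$selected, 1L)

  # unscorable candidates rank last
  tab$ccc[1] <- NA
  expect_equal(rank_and_select(tab)$ranking$ccc[3], NA_real_)
  tab$ccc <- NA_real_
  expect_error(rank_and_select(tab), "no scorable")
})

test_that("rank_and_select accepts candidate_result lists", {
  cands <- list(
    evaluate_candidate(quiet_dev, quiet_study$true_params),
    evaluate_candidate(quiet_dev,
                       dd_params("simple", lower = 0, upper = 37,
                                 biofix = "01-01"))
  )
  rep1 <- rank_and_select(cands)
  expect_equal(rep1$selected, 1L)
  expect_equal(rep1$n_candidates, 2L)
})

test_that("grid search reproduces standalone candidate evaluation", {
  spec <- grid_spec(lower_f = c(58, 60), upper_f = c(70, 72),
                    start_dates = c("01-01", "03-01"))
  report <- grid_search(quiet_dev, spec)
  expect_equal(report$n_candidates, 3 * 3 * 2 * 2)
  # pick an arbitrary row and recompute it standalone
  row <- report$candidates[7, ]
  cand <- evaluate_candidate(
    quiet_dev,
    dd_params(row$method, lower = row$lower, upper = row$upper,
              biofix = row$start))
  expect_equal(row$aic, cand$fit$aic)
  expect_equal(row$ccc, cand$agreement$ccc)
  expect_equal(row$dd_target, cand$dd_target)
  expect_equal(row$slope, cand$fit$curve$slope)
})

test_that("start dates are interchangeable when no degree-days accrue early", {
  # lower threshold 15 degC: with a noise-free Minnesota-like seasonal cycle
  # nothing accumulates before April 1, so all four start dates coincide
  spec <- grid_spec(lower_f = c(59, 59), upper_f = c(71, 71))
  report <- grid_search(quiet_dev, spec)
  expect_equal(report$n_candidates, 8L)
  for (m in c("simple", "sine")) {
    rows <- report$candidates[report$candidates$method == m, ]
    expect_equal(length(unique(rows$ccc)), 1L)
    expect_equal(length(unique(rows$aic)), 1L)
  }
})

test_that("low-noise synthetic data recover thresholds and dd10", {
  # focused grid around the generating 15/21.7 degC model
  spec <- grid_spec(lower_f = c(55, 63), upper_f = c(67, 75),
                    start_dates = "01-01")
  report <- grid_search(quiet_dev, spec)
  top <- report$ranking[1, ]
  expect_equal(top$lower, 15, tolerance = 1.13 / 15)       # within 2 grid steps
  expect_equal(top$upper, 21.7, tolerance = 1.13 / 21.7)
  truth <- dd_at_proportion(quiet_study$true_curve, 0.10)
  cand <- evaluate_candidate(quiet_dev, quiet_study$true_params)
  expect_equal(cand$dd_target, truth, tolerance = 0.05)
})
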