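---
title: "Degree-day models for trap-catch phenology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-day models for trap-catch phenology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodd)
```

`phenodd` implements a complete development-and-validation pipeline for
degree-day models of adult insect trap-catch phenology, of the kind used for
Japanese beetle monitoring in the upper Midwest. This vignette explains the
model, the assumptions baked into each stage, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate about field data.

## The model

The biological premise is that the seasonal timing of adult activity is
driven by thermal accumulation rather than by the calendar: a univoltine
population emerges when enough heat has accumulated above its lower
developmental threshold. The observable is trap-catch — counts (or sample
volumes) from semiochemical-baited traps, visited once or twice a week — and
the modelled quantity is the *cumulative proportion of the seasonal catch*,
which removes the large between-site differences in absolute abundance.

Accumulated degree-days $D$ (°C·days) enter a log-logistic emergence curve

$$p(D) = \frac{e^{s\,\ln D + i}}{1 + e^{s\,\ln D + i}},$$

a logistic regression on natural-log degree-days with slope $s$ and intercept
$i$. Taking $\ln D$ rather than $D$ lets the curve rise steeply after a slow
start, which matches observed emergence; it also makes the curve exactly
invertible, $D(p) = \exp\{(\mathrm{logit}(p) - i)/s\}$, which is how
degree-day requirements at the 10/25/50/75/90% forecast points are obtained
(`dd_at_proportion()`, `dd_percentiles()`).

The assumptions worth stating: catch proportion is a monotone function of
accumulated heat alone (no photoperiod, rainfall, immigration or lure-decay
terms); all site-years share one curve (testable — see the covariate F test
below); and air temperature at a nearby station is an adequate proxy for the
thermal environment of the soil-dwelling immatures.

## Degree-day calculators

Two daily calculators are provided, both parameterised by lower and upper
developmental thresholds $T_L < T_U$ (°C) and both clamped to
$[0,\,T_U - T_L]$ per day:

* **Simple average (method 1).** With $\bar T = (t_{\min}+t_{\max})/2$, the
  day yields $\max(0, \min(\bar T, T_U) - T_L)$. The extremes are *not*
  clamped before averaging (that would be the other common simple method),
  and the upper threshold acts as a **horizontal cutoff**: heat above $T_U$
  counts as if the day sat at $T_U$, rather than being subtracted. The same
  horizontal-cutoff convention is used in the sine method, so the two differ
  only in how they interpolate within the day.
* **Half-day sine-wave.** Each half-day is modelled as
  $T(\theta) = m + \alpha\sin\theta$, $\theta \in [-\pi/2, \pi/2]$, through
  its bounding extremes; the contribution is
  $\tfrac{1}{2\pi}\int \max(0, \min(T(\theta), T_U) - T_L)\,d\theta$,
  evaluated in closed form over the six configurations of the extremes
  relative to the thresholds. The closed form is verified in the test suite
  against midpoint-rule quadrature at $2\times10^5$ nodes over more than
  1,000 randomized cases stratified across all six branches (agreement within
  $10^{-6}$ °C·days). A constant trace ($\alpha = 0$) degenerates to half the
  clamped excess. By default the second half-day runs from the day's maximum
  down to the *following* day's minimum (the double-sine convention;
  `sine_second_half = "same_day_tmin"` switches to single-sine), and the last
  day of a series reuses its own minimum since no following day exists. If a
  following morning is warmer than the day's maximum the half-day endpoints
  are re-ordered rather than rejected.

Accumulation starts at a **biofix** date, stored as month-and-day and
resolved per calendar year so that leap years are handled by the calendar
("03-01" is Julian 61 in 2020 and 60 in 2021). A literal-Julian mode is also
available (`biofix = 60`) because fixed Julian indices — including the
conventional Midwest start-date set {1, 32, 50, 91}, whose "50" does not
correspond to March 1 by calendar arithmetic — are in practical use;
`grid_spec()` accepts either form and neither is second-guessed. Cumulative
degree-days are end-of-day totals, zero on the day before the biofix, and
`date_at_dd()` inverts the accumulation by linear interpolation inside the
crossing day (a first-crossing-day ceiling is available via
`interpolate = FALSE`). A target beyond the season's total returns `NA` — a
"not reached" signal distinct from an error, which matters during grid search
where extreme thresholds routinely starve a cool site-year.

## From raw traps to curves

`build_curve()` pools traps within a site-date by summing, then divides the
running total by the seasonal total. Pooling (rather than averaging per trap)
gives identical proportions when every trap is observed on every date and
degrades gracefully when one is lost. Counts and volumetric measurements are
interchangeable because only proportions enter the model. Observed dates at a
target proportion are linearly interpolated **on the calendar-day axis** by
default; interpolating on the degree-day axis and mapping back through the
accumulation is available (`axis = "degree-day"`) and coincides with the
day-axis answer whenever accumulation is locally linear. A first observation
already above the target is returned as-is with a left-censoring warning.

## Fitting the emergence curve

`fit_log_logistic()` maximises the unit-weight Bernoulli-form log-likelihood
$\ell = \sum_k [y_k \ln \hat p_k + (1-y_k)\ln(1-\hat p_k)]$ over $(s, i)$,
one row per site-year × observation date. This is deliberately *not* a
count-weighted binomial fit over the tens of thousands of trapped beetles:
cumulative counts within a season are strongly serially dependent, so beetle-
level weights drastically overstate the information content; the unit-weight
form treats the observation date as the replication unit. (Count weighting
remains available behind the `weights` argument.) Consequences to keep in
mind: reported AIC ($2k - 2\ell$, $k = 2$; dispersion not counted) is
comparable *across candidates on the same data*, not across data sets of
different size.

Numerics: iteratively reweighted least squares with deterministic
initialisation from the least-squares line of empirical logits ($y$ clamped
to $[0.005, 0.995]$ for initialisation only), convergence when the deviance
changes by less than $10^{-10}$ (at most 100 iterations), and a BFGS fall-back
on the negative log-likelihood if IRLS stalls; the better of the two
candidates by likelihood is kept. Cumulative proportions of exactly 0
(pre-emergence visits) or 1 (the final visit) are retained — their likelihood
terms use the defined limits — and observation dates with zero accumulated
degree-days are dropped, as $\ln D$ is undefined there. The tests check the
optimiser against `glm(family = binomial)` on fractional responses and
against a brute-force likelihood grid.

The **site-year covariate test** (`site_year_covariate_test()`) compares the
pooled curve against group-specific intercepts or slopes with the
deviance-based F statistic
$F = \{(\mathrm{Dev}_{red} - \mathrm{Dev}_{full})/\Delta df\}\,/\,
\{\mathrm{Dev}_{full}/df_{full}\}$. The deviances entering $F$ are
*residual* (saturated-model-relative) deviances: the numerator difference is
identical under either convention, but using $-2\ell$ in the denominator
would fold the intrinsic Bernoulli entropy into the dispersion estimate and
drive the type-I error to zero. With residual deviances the test is
approximately calibrated — the suite's Monte-Carlo null (400 replicates of
binomial-sampled proportions) rejects at 3–5% for a nominal 5% — while any
serial dependence in real cumulative curves will still make it conservative
or liberal in ways simulation with independent errors cannot reveal.

## Grid search, scoring and selection

`grid_spec()` defaults to lower thresholds 32–59 °F and upper thresholds
68–100 °F in 1 °F (0.56 °C) steps, four start dates and both methods:
$28 \times 33 \times 4 \times 2 = 7{,}392$ candidates. The grid is specified
in Fahrenheit because the 1 °F increment is the grid's native resolution —
the count of 7,392 is only consistent with whole-°F endpoints (a 20–37 °C
reading of the upper range yields 31, not 33, values); conversion to Celsius
happens once at enumeration. Enumeration order (method, start date, lower,
upper) is part of the contract, because it is the final tie-break in ranking.

Each candidate is scored by Lin's concordance correlation coefficient
between predicted and observed Julian dates of 10% trap-catch across the
development site-years,

$$CCC = \frac{2\,\mathrm{cov}(x,y)}{\sigma_x^2 + \sigma_y^2 +
(\bar x - \bar y)^2} = r \cdot A,$$

computed with population ($1/n$) moments; $r$ is precision, $A = CCC/r$ the
accuracy (bias-correction) factor. CCC is the right score here because the
goal is *agreement with the 1:1 line*, not mere correlation — a model that
predicts every site-year three days early can have $r = 1$ but is penalised
through $A$. Ranking is CCC descending, AIC ascending, enumeration order;
candidates whose degree-day requirement goes unmet in all but one site-year
are unscorable and rank last rather than aborting the search. The selected
candidate's rank under AIC alone is reported as a fit-across-the-curve
diagnostic. `grid_search()` shares each method/threshold cell's daily
degree-day vectors across the four start dates; the tests verify bit-identical
agreement with standalone `evaluate_candidate()` calls, and site-year order
is immaterial by construction.

`validate_model()` applies the selected curve's degree-day requirement to
hold-out site-years, reporting errors as predicted − observed days (negative
= model early), the sample ($n-1$) standard deviation, the range, and CCC.

## The synthetic study generator

Field trap-catch data sets of this kind are rarely deposited, so the
generator is a first-class module, not a test fixture. It emulates:

* **Weather** — daily mean
  $\bar T(d) = \mu + a \sin\{2\pi(d - d_{peak} + 91.25)/365.25\}$ plus AR(1)
  noise ($e_d = \rho e_{d-1} + \varepsilon_d$, stationary start), with
  constant diurnal range split symmetrically. Defaults are a Minnesota-like
  climate — annual mean 7 °C, amplitude 16 °C, warmest day 200, diurnal range
  10 °C, innovation SD 3 °C, $\rho = 0.6$ — chosen so a 15 °C lower threshold
  puts 10% trap-catch in late June–July, the observed adult activity window.
  The AR(1) term matters: independent noise would never produce the multi-day
  warm spells that generate realistic accumulation bursts and stress the
  within-day interpolation of `date_at_dd()`.
* **Trap catch** — expected cumulative proportion at each visit is the true
  curve evaluated at the true accumulation; interval expectations are the
  successive differences (the first visit absorbs the pre-deployment catch, a
  terminal remainder is folded into the last visit so expectations sum to 1);
  realised counts are multinomial with the season total (or independent
  Poisson), split at random across four trap ids. Visits run twice weekly
  (3.5-day spacing rounded to alternating 3/4-day calendar steps) from Julian
  day 150 — a late-May deployment ahead of emergence — until the true curve
  passes 99.5%. Default season total is 10,000 per site-year, the order of
  magnitude of the motivating field counts.
* **A study** — `generate_study()` jitters each site-year's annual mean
  (SD 0.8 °C) and seasonal peak (SD 4 d) to create between-site phenology
  variation, cycles the years 2019–2021 (including a leap year), and can
  write the CSVs plus a YAML manifest for `run_pipeline()`. All randomness
  flows from one seed.

What the generator does *not* emulate — and hence what passing tests cannot
certify about field data: trap saturation and lure decay, immigration pulses
and dispersal, rainfall-suppressed flight, missing trap visits, weather-
station-to-site mismatch, and any dispersion in counts beyond
multinomial/Poisson sampling (no field estimate of that dispersion exists to
calibrate against). Recovery results on synthetic data therefore demonstrate
the *pipeline's* correctness and stability, not field predictive skill.

## Problem sizes and numerical defaults

The test suite runs the full 7,392-candidate search once, on a 6 + 6
site-year synthetic study (≈370 pooled observations), about half a minute of
compute; other tests use focused sub-grids (tens to hundreds of candidates)
and 1,000+ randomized property cases. Selected thresholds on such a study
land within one-to-two 1 °F grid steps of the generating values, and the
fitted slope and intercept land within about 1% of truth at the generating
parameters; the degree-day scale's sensitivity to the upper threshold means a
one-step threshold miss shifts the *nominal* degree-day requirement by a few
percent while barely moving predicted dates — which is exactly why selection
scores date agreement rather than coefficient recovery.

Key numeric defaults, in one place: IRLS tolerance $10^{-10}$ (absolute
deviance change), 100 iterations, logit-clamp 0.005 for initialisation;
likelihood probability floor $10^{-15}$; sine/quadrature test tolerance
$10^{-6}$ °C·days; `date_at_dd()` and observed-date interpolation are exact
linear interpolations with no tolerance; ties in ranking broken by AIC then
enumeration order; unscorable candidates never abort a search.

## Known limitations

* The emergence curve is a single sigmoid: bimodal seasons (split emergence,
  strong immigration) will fit poorly and the AIC column is the only hint.
* The covariate F test assumes independent observation-date errors;
  cumulative curves are serially dependent, so treat its p-values as
  descriptive.
* Degree-day requirements are tied to the threshold pair that produced them;
  requirements from different candidates are on different scales and must not
  be compared numerically.
* The generator's noise defaults are plausible rather than calibrated — no
  published dispersion estimate exists for trap counts about the fitted
  curve — and they are deliberately exposed in the configuration objects.
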