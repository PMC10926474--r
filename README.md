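# phenodd

Degree-day phenology models for insect trap-catch data.

`phenodd` develops and validates degree-day models that forecast the seasonal
phenology of adult insect trap-catch — the kind of model used to tell growers
and regulatory staff when Japanese beetle (*Popillia japonica*) activity will
reach 10% of its seasonal total, early enough to plan scouting and management.
It is aimed at entomologists and IPM modellers who have daily min/max air
temperatures and semiochemical-trap counts for a handful of site-years and
want a reproducible pipeline from raw CSVs to a selected, validated model.

## The model

Degree-days accumulate daily from a biofix date (here Jan 1) between a lower
and an upper developmental threshold, `T_L < T_U`, by either

* the **simple average** (method 1): `DD = max(0, min((tmin + tmax)/2, T_U) - T_L)`,
  with a horizontal cutoff at `T_U` and no pre-clamping of the extremes; or
* the **half-day sine-wave** method: the day's temperature trace is modelled
  per half-day as `T(θ) = m + α sin θ`, `θ ∈ [-π/2, π/2]`, through the daily
  extremes, and the thresholded area `(1/2π) ∫ max(0, min(T, T_U) - T_L) dθ`
  is accumulated in closed form.

The cumulative proportion of seasonal trap-catch `p` is related to
accumulated degree-days `D` by a log-logistic emergence curve

```
p(D) = exp(s·ln D + i) / (1 + exp(s·ln D + i))
```

with slope `s` and intercept `i` fitted by maximum likelihood (unit-weight
Bernoulli form, IRLS). Model development is an exhaustive grid search over
biofix dates (Jan 1 / Feb 1 / Mar 1 / Apr 1), lower thresholds 32–59 °F,
upper thresholds 68–100 °F (1 °F steps) and both calculation methods — 7,392
candidates — each scored by Lin's concordance correlation coefficient
(`CCC = r·A`, precision × accuracy) between predicted and observed dates of
10% trap-catch, with AIC as tie-break. A hold-out set of site-years provides
validation statistics (mean/min/max error in days, sample SD, CCC).

Because field trap data of this kind are rarely deposited, the package ships
a synthetic study generator (seasonal-sinusoid weather with AR(1) noise,
multinomial trap counts following a known emergence curve) so the entire
pipeline can be exercised and tested at desk scale.

## Worked example

Forecast percentiles from a fitted emergence curve (slope 7.41, intercept
−43.34, degree-days in °C from a 15/21.7 °C simple model):

```r
library(phenodd)
curve <- emergence_curve(slope = 7.41, intercept = -43.34)
dd_percentiles(curve)
#> # A tibble: 5 × 3
#>   proportion  dd_c  dd_f
#>        <dbl> <dbl> <dbl>
#> 1       0.1   258.  464.
#> 2       0.25  299.  538.
#> 3       0.5   347.  624.
#> 4       0.75  402.  724.
#> 5       0.9   467.  840.
```

so 10% of the seasonal catch is expected by ~258 °C degree-days and peak
(50%) by ~347. A full development/validation round on synthetic data:

```r
study <- generate_study(n_dev = 6, n_val = 6, seed = 1)   # truth: simple, 15/21.7 °C
dev   <- study_site_years(study, "development")

report <- grid_search(dev, grid_spec(lower_f = c(55, 63), upper_f = c(67, 75),
                                     start_dates = "01-01"))
report
#> <selection_report> 162 candidates; selected #40: simple 15.00/21.11 degC, start 01-01
#>   CCC = 0.9991, AIC = 159.325 (AIC-alone rank 4 of 162)

validate_model(report$selected_result, study_site_years(study, "validation"))
#> <validation_stats> 6 site-years at p = 0.10 (DD requirement 244.8)
#>   mean error 0.22 d (sd 0.693, range -0.81 to 1.31)
#>   CCC = 0.9945 (r = 0.9961, A = 0.9984)
```

The search recovers the generating lower threshold exactly and the upper
threshold to within one 1 °F grid step; hold-out predictions of the 10% date
land within a day of the observed dates. `grid_spec()` with no arguments runs
the full 7,392-candidate grid (about half a minute for six site-years), and
`run_pipeline(manifest, out_dir)` drives the whole sequence from a YAML study
manifest to CSV/JSON artifacts (ranked candidates, selection, validation
table, percentile table).

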