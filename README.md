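# fireits

Two-stage interrupted time series for estimating **excess outpatient and
virtual acute-care visits after an abrupt environmental disaster**, built
for daily electronic-health-record visit counts stratified by wildfire
exposure zone, care setting and cause category. It is aimed at
epidemiologists and health-system analysts who need a rapid, reproducible
answer to "how much more care did people seek than we would have expected
without the event?" — together with honest empirical uncertainty.

## What it does

For each stratum (exposure zone × setting × cause), with daily counts
$y_t$ and exogenous covariates $x_t$ (daily meteorology, weekly wastewater
virus levels):

1. **Stage 1 — counterfactual.** On pre-event data only, fit a hybrid
   model: a log-link quasi-Poisson structural regression
   $\log\mu_t = \alpha + \beta t + \sum_k [a_k\sin(2\pi k t) + b_k\cos(2\pi k t)] + \gamma_{\mathrm{dow}(t)} + \delta\,\mathrm{hol}(t)$
   plus a gradient-boosted corrector trained on relative residuals from
   covariates and calendar features (never lagged counts). Hyperparameters
   are selected by minimizing RMSE across rolling-origin cross-validation
   folds; the winner predicts the post-event window from calendar and
   covariate inputs alone.
2. **Stage 2 — excess inference.** Cumulative excess
   $\sum_W (y_t - \hat y_t)$ and percent excess
   $100\sum_W(y_t-\hat y_t)/\sum_W \hat y_t$ over the post-event window,
   with 95% empirical CIs from 1000 Monte Carlo iterations of a
   season-matched, variance-standardized moving-block bootstrap of
   pre-period residuals around the counterfactual.

Supporting modules: distance-buffer exposure zoning of census tracts
against burn-zone polygons (high < 20 km; moderate ≥ 20 km within the
impacted county; minimal elsewhere; 10 km sensitivity), ICD-10 range
classification (cardiovascular I00–I99, injury S00–T88, neuropsychiatric
F01–F99, respiratory J00–J99), cohort characteristics tables, market-share
extrapolation of excess to the full insured population, and a synthetic
EHR generator with known injected effects for end-to-end validation.
See the methods vignette (`vignettes/wildfire-its.Rmd`) for the model,
defaults and design rationale.

## Worked example

Simulate a 26-month study in which high-exposure virtual respiratory
visits are raised 40% for the week after the 2025-01-07 event, then recover
the effect:

```r
library(fireits)

scenario <- synthetic_scenario(
  baseline_rate = 80, settings = "virtual", causes = "respiratory",
  n_tracts_per_zone = c(high = 6L, moderate = 8L, minimal = 6L),
  injected_effects = list(list(
    zone = "high", setting = "virtual", cause = "respiratory",
    start = "2025-01-07", end = "2025-01-13", multiplier = 1.4)),
  seed = 42)

study <- simulate_study(scenario, n_members = 5000)
table(study$zoning$zone)
#>     high  minimal moderate
#>        6        6        8

res <- estimate_stratum_excess(
  study$visits, study$covariates,
  zone = "high", setting = "virtual", cause = "respiratory",
  pre_end = scenario$event_date, n_iter = 1000, seed = 42)

res$fit
#> <counterfactual_fit> high/virtual/respiratory
#>   selected: structural_seasonal/K8/cp0/hol/gb(d2,eta0.05,n200)
#>   mean CV RMSE: 16.645 visits/day over 6 candidate(s)
#>   pre-period: 2022-11-01 .. 2025-01-06 (798 days, 0 clipped predictions)

round(res$cumulative[, c("observed","predicted","excess","pct_excess",
                         "ci_low","ci_high")], 1)
#>   observed predicted excess pct_excess ci_low ci_high
#> 1     1094     819.7  274.3       33.5   21.7    50.9
```

Reading the output: cross-validation selected the order-8 Fourier base with
a depth-2 boosted covariate corrector; 1094 visits were observed in the
week against a counterfactual of ~820, i.e. 274 excess visits or +33.5%
(95% empirical CI 21.7–50.9%), an interval covering the injected +40%
truth. `daily_excess_profile()` gives the per-day breakdown and
`plot_excess()` the points-and-whiskers figure;
`extrapolate_excess(..., c(high = 0.136))` scales cohort excess to the full
insured population of the zone.

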