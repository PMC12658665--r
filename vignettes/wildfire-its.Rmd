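---
title: "Estimating excess acute-care visits after an abrupt environmental disaster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating excess acute-care visits after an abrupt environmental disaster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An abrupt environmental disaster — here, urban wildfires igniting in a
populated basin — changes how people seek acute care. Smoke, evacuation,
psychosocial stress and community disruption can raise outpatient and
virtual visit volumes within days, but the counterfactual ("how many visits
would have occurred without the event?") is unobservable. `fireits`
implements a two-stage interrupted time-series (ITS) estimator of excess
visits for daily count series stratified by exposure zone, care setting and
cause category, together with the surrounding machinery a full analysis
needs: distance-buffer exposure zoning, ICD-10 range classification,
insured-population extrapolation, and a synthetic EHR generator with known
injected effects so the whole pipeline can be validated end to end.

## Stage 1: the hybrid counterfactual

For one stratum, let $y_t$ be the daily visit count over a pre-event period
and $x_t$ a vector of exogenous covariates (daily meteorology, weekly
wastewater virus levels). The base learner is a log-link quasi-Poisson
regression

$$\log \mu_t = \alpha + \beta t + \sum_{k=1}^{K}\left[a_k \sin(2\pi k t) +
b_k \cos(2\pi k t)\right] + \sum_{d} \gamma_d \,\mathrm{dow}_d(t) +
\delta\,\mathrm{hol}(t),$$

with $t$ in years, $K$ annual Fourier harmonics, day-of-week indicators and
a holiday indicator (federal holidays plus December 24–January 1). The log
link matters: trend, weekly cycle, seasonality and holiday dips act
*multiplicatively* on a visit rate, and an additive fit misallocates the
winter holiday dip into the seasonal curve exactly where the post-event
window sits. An optional trend-changepoint basis (`trend_flexibility`)
exists, but the default candidate grid excludes it: flexible trends earn
their keep in-sample while the last, thinly-estimated segment dominates the
boundary extrapolation a short post-event forecast relies on.

The residual corrector is gradient boosting (`xgboost`) on the *relative*
residuals $(y_t - \hat\mu_t)/\hat\mu_t$, with features limited to z-scored
covariates, day-of-week and holiday indicators — never lagged counts, which
would smuggle the post-event outcome into its own counterfactual.
Covariate effects on counts are approximately multiplicative, so the
relative scale presents the booster with a nearly linear, homoscedastic
target instead of a signal drowned in level-dependent count noise. The
corrector is strongly regularized by default (depth 2, learning rate 0.05,
200 rounds, `min_child_weight` 30, L2 penalty 10): its true signal is weak
and concentrated in the respiratory season, and an unregularized booster
loses cross-validation everywhere else, pushing model selection toward
covariate-blind configurations that extrapolate poorly.

### Model selection

Candidates are compared by mean RMSE over rolling-origin cross-validation
folds fit strictly inside the pre-period; the winner is refit on the full
pre-period, with ties resolved toward the earlier (simpler) entry. The
default scheme uses 10 folds of 7 validation days, ending at the last
pre-event day. Matching the validation horizon to the 7-day deployment
horizon, and concentrating validation on the weeks leading up to the event,
discriminates much better between covariate-using and covariate-blind
candidates than a few long windows spread over the preceding year; both the
fold count and window length are configurable via `cv_scheme()`.

## Stage 2: excess and empirical confidence intervals

Over a post-event window $W$, cumulative excess is
$\sum_{t \in W}(y_t - \hat y_t)$ and percent excess is
$100 \sum_W (y_t - \hat y_t) / \sum_W \hat y_t$. Uncertainty comes from a
Monte Carlo procedure (default 1000 iterations): each iteration adds a
circular moving-block bootstrap sample (default block length 7 days) of
pre-period residuals to the point predictions, floors the perturbed
counterfactual at zero, and recomputes percent excess; the 95% empirical CI
is the 2.5th/97.5th percentile across iterations. Daily and cumulative
estimates share the same draws, so each iteration's daily excesses sum
exactly to its cumulative excess.

Three refinements keep the interval honest for count data:

* **Seasonal sampling.** Block starts are restricted to pre-period days
  whose day-of-year lies within 45 days of the window (`season_half_width`);
  winter residuals are larger and more structured than summer ones.
* **Variance standardization.** Each resampled residual is divided by the
  negative-binomial standard deviation of its source day
  ($\sqrt{\hat\mu + \hat\mu^2/\hat k}$, with $\hat k$ a moment estimate from
  the residuals) and rescaled to the predicted window day. A January window
  sits at the seasonal peak of both the rate and its variance; transferring
  raw residual magnitudes from lower-count days understates it.
* **Out-of-sample inflation.** Draws are stretched by the ratio of
  cross-validated to in-sample RMSE (floored at 1): a fitted curve absorbs
  part of the noise it will face out of sample, and flexible candidates
  absorb more.

The low-level `monte_carlo_excess()` applies the plain additive mechanism to
explicit prediction/residual vectors; the fit-level wrappers apply all three
refinements. A slow `mode = "refit"` re-estimates the selected
configuration on a bootstrap-perturbed pre-period in every iteration,
propagating parameter uncertainty instead; it is exposed because the number
of defensible Monte Carlo mechanisms exceeds what any one default can
settle.

Percent excess is undefined for iterations whose perturbed prediction is
floored to zero; these drop out of the percent quantiles (count-scale
quantiles keep them). All-zero residuals yield a degenerate interval and a
warning.

## Exposure zoning

Census tracts are classified a priori by the great-circle distance from
their representative point to the nearest burn-zone polygon boundary
(haversine on a sphere of radius 6371.0088 km; a point inside a polygon is
at distance 0). Strictly less than the buffer (20 km primary, 10 km
sensitivity) is *high* exposure; at or beyond the buffer it is *moderate*
inside the impacted county and *minimal* outside. The boundary tie goes to
not-high, matching the "within 20 km" versus "20 km or more" definitions.
Representative points rather than tract polygons anchor the distance because
tract geometry is not modeled; at these scales the choice moves tracts near
the buffer boundary only. Taking the minimum over fire polygons unions
overlapping burn zones implicitly. Segment distances use a clamped
cross-track construction with the numerically stable tangent form of the
along-track distance — the naive $\arccos(\cos/\cos)$ identity loses
precision exactly in the near-zone cases that decide classifications.

## ICD-10 cause categories

A code's 3-character root (letter + two digits) decides membership,
compared lexicographically against inclusive ranges: cardiovascular
I00–I99, injury S00–T88 (so T50 is injury), neuropsychiatric F01–F99 (F00
is excluded), respiratory J00–J99; every valid code is also `all_cause`.
Subcodes never change the category. An encounter listing codes in several
ranges increments each matched cause once and `all_cause` exactly once — a
de-duplication rule the package fixes explicitly because source systems
rarely state one. Aggregation always produces a dense date × zone ×
setting × cause grid with explicit zeros so downstream models see every
calendar day.

## Reporting

`cohort_table()` builds a characteristics table (counts with percents, and
median (IQR) age via linear-interpolation quartiles) by exposure zone.
Percents round half-up to one decimal; any nonzero share below 0.05%
renders `"<0.1"` rather than a misleading `"0.0"`, applied uniformly.
`extrapolate_excess()` divides cohort excess — point estimate and CI bounds
alike — by each zone's market-share coverage fraction (the share of the
insured population the analyzed cohort represents there) and sums across
zones; coverage fractions are user-supplied configuration, since only
published values for specific zones exist.

## The synthetic generator

`synthetic_scenario()` + `simulate_study()` emulate the statistical
structure the analysis assumes, with every generative parameter known:

* 26-month daily window (2022-11-01 to 2025-01-21) with an event on
  2025-01-07;
* cell mean `baseline × trend × weekly × annual × holiday ×
  exp(Σ β·z-scored covariate) × injected multiplier`, with weekend levels
  below weekdays (outpatient more suppressed than virtual care), a
  winter-peaking annual cycle (default relative amplitude 0.10), and a
  holiday multiplier (default 0.6);
* negative-binomial counts with dispersion `k` (default 50; `Inf` gives
  Poisson) — daily visit counts are overdispersed, and the marginal count
  distribution is this module's assumption, not an established fact;
* covariates with sinusoidal annual cycles and additive noise, wastewater
  levels piecewise-constant within ISO weeks (log-scale winter-peaking
  cycle with weekly noise), shared across zones as a county-level signal;
* counts drawn by inverting one uniform per cell through the
  negative-binomial quantile function, so configuring an injected effect in
  one cell never perturbs the draws of any other cell (a property the
  injection-locality tests rely on);
* one master seed with deterministic per-stream child seeds.

What it deliberately does **not** emulate: smooth multi-week epidemic waves
(wastewater noise is independent across weeks), spatial smoke gradients
within a zone, member-level encounter timing, care-seeking behavior change,
or reporting lags. Passing parameter-recovery tests on this generator
therefore shows the estimator recovers known multiplicative effects under
realistic seasonality, overdispersion and covariate dependence — not that
any particular real-world estimate is correct.

## Validation design and problem sizes

The test suite validates each module against independent oracles
(closed-form haversine distances and dense boundary sampling for zoning,
binomial/Poisson moment bounds for the generator, hand-computed RMSE and
excess values) and the whole pipeline by parameter recovery: 20 replicate
synthetic datasets with a 1.4× multiplier injected into one stratum
(baseline 80 visits/day) must recover 40% excess within 5 percentage points
on average with the 95% CI covering the truth in at least 17, and a null
(multiplier 1.0) run must not exclude zero in more than 3. Replicates use
the default candidate grid and 500 Monte Carlo iterations — sizes chosen to
exercise the full selection-and-inference path on a single stratum; the
acceptance script runs one full study at 1000 iterations.

## Known limitations

* Counterfactual uncertainty from model *selection* is only partially
  reflected by the CV-inflation factor; a config that cross-validates well
  but extrapolates badly in one realization can still produce an interval
  that misses.
* The extrapolation step assumes excess scales inversely with coverage —
  i.e., cohort members are representative of the zone's insured population.
* Tract classification ignores tract polygons and population weighting.
* The refit Monte Carlo mode refits the selected configuration only; it
  does not re-run model selection per iteration.
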