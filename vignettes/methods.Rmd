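---
title: "Methods: temperature-percentile DLNM and climate-change attribution of neonatal deaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-percentile DLNM and climate-change attribution of neonatal deaths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Newborns are unusually vulnerable to both heat and cold: immature
thermoregulation, a high surface-area-to-mass ratio, and high metabolic
rates narrow the band of ambient temperatures they tolerate. `neonatclim`
estimates (i) how the daily risk of neonatal death (age 0--28 days; with a
separate option for deaths on the day of birth) depends on ambient
temperature, and (ii) how many of the temperature-related deaths over a
study window are attributable to the long-term warming trend -- that is,
the difference in the burden between a *factual* temperature series and a
*counterfactual* series from which the climate-change signal has been
removed while the day-to-day weather variability is kept.

The pipeline has two stages.

# Stage one: the exposure-response model

## Percentile standardisation

Populations live in very different climates, and what counts as a "hot"
day in a highland town is an ordinary day in the lowlands. Before pooling
locations we therefore convert absolute daily mean temperatures into
*location-specific percentiles*. `fit_percentile_map()` builds an
empirical map from a location's reference sample using the Hazen plotting
position,

$$\mathrm{pct}(x) = 100\,\frac{\mathrm{rank}(x) - 0.5}{n},$$

with mid-ranks for ties, linear interpolation between observed values, and
clamping to the extreme Hazen percentiles outside the observed range. The
Hazen convention is symmetric and never returns 0 or 100, which keeps the
spline basis away from degenerate boundary values; alternative plotting
positions would change percentiles by at most $O(1/n)$ on multi-year daily
reference samples.

The reference sample is the location's **factual** series over the study
window, and the counterfactual series is pushed through the *same* map.
This is a deliberate design choice: the fitted exposure-response curve is
indexed by the factual percentile scale, and expressing both scenarios on
one common scale is what makes a single coefficient vector applicable to
both when the burden is computed. Percentiles, being ranks, are invariant
to any strictly monotone rescaling of the temperature data, which the test
suite checks as a property.

## Time-stratified case-crossover design

Each death day (the *case day*) is compared with *control days* that fall
on the same day of the week within the same calendar month and year
(`build_matched_sets()`). Every stratum of that kind holds 4 or 5 days, so
each case gets 3 or 4 controls. The design is self-matched: time-invariant
characteristics of the child, the household and the location cancel by
construction, the same-weekday restriction removes weekly cycles, and the
same-month-and-year restriction removes seasonality and long-term trends.
The referent window is the calendar month of the death -- not a window
centred on it -- matching the standard time-stratified scheme, which is
immune to the overlap bias of symmetric bidirectional designs. Sets whose
lag window falls outside the available exposure series are dropped and
counted, never imputed.

## Distributed lag non-linear model

Temperature affects mortality non-linearly (a U-shape with a minimum at
some optimal percentile) and with delay (a hot day can kill today and
tomorrow). Both dimensions are modelled jointly with a *cross-basis*: the
tensor product of a natural cubic spline in the exposure percentile and a
natural cubic spline in the lag. For lagged exposures
$x_{t-l_0},\dots,x_{t-L}$ the covariate vector has entries

$$C_{ij}(t) = \sum_{l=l_0}^{L} b^{\mathrm{var}}_i(x_{t-l})\,
  b^{\mathrm{lag}}_j(l).$$

Defaults (all configurable through `cross_basis_spec()`):

* **Lag window** 0--2 days (`lag_spec(0, 2)`): temperature effects on
  neonatal deaths are acute; for deaths on the day of birth the window
  covers the two days before delivery plus the birth day itself.
* **Exposure spline**: one internal knot at the 20th percentile, boundary
  knots at 0 and 100, no intercept (2 df). The single low knot gives the
  cold arm -- where neonatal risk is typically steeper -- more curvature.
  A knot at the 10th percentile is conventional for day-of-birth deaths
  (`cross_basis_spec(var_knots = 10)`).
* **Lag spline**: one internal knot at equally spaced log-lag values
  (`log_lag_knots()`, $\sqrt{2}\approx 1.414$ for a 0--2 window), boundary
  knots at the lag bounds, with intercept (3 df). Log spacing concentrates
  flexibility at short lags, where the effect changes fastest. The exact
  lag-basis dimension is an interpretation choice; it is configurable, and
  a constant (intercept-only) lag basis is available, under which the
  framework provably collapses to an ordinary one-dimensional spline model
  (tested).

The default model therefore has $2 \times 3 = 6$ coefficients.

## Conditional logistic fit

With one case and $M-1$ controls per set, the exact conditional likelihood

$$\ell(\beta) = \sum_{s} \Big[\eta_{s,\mathrm{case}} -
  \log \sum_{j \in s} e^{\eta_{s,j}}\Big], \qquad \eta = C\beta,$$

is maximised by Newton-Raphson with step-halving (`clogit_fit()`).
Numerical choices: convergence requires a relative log-likelihood change
below $10^{-10}$ *and* a gradient max-norm below $10^{-6}$, capped at 100
iterations -- appropriate for the small, well-conditioned coefficient
count; log-sum-exp terms are centred on the within-set maximum so long
linear predictors cannot overflow; divergence of any coefficient past 50
while the likelihood still climbs is reported as complete separation ("no
finite MLE") rather than returned as an estimate. Uninformative sets
(identical case and control covariates) are retained -- they contribute a
constant, preserving the identity $\ell(0) = -\sum_s \log M_s$ -- but a
design with *no* informative set is an error. The covariance matrix is
the inverse observed information at the optimum. The fit is invariant to
adding any set-constant vector to the covariates, which is why the
cross-basis needs no explicit centring during estimation: the reference
enters only through contrasts, afterwards.

Several candidate knot placements can be compared with `aic_select()`
(AIC $= 2k - 2\ell$); ties resolve to the first candidate and failing
candidates (e.g. a knot placement that makes the design singular) are
skipped with a log entry.

## Minimum-mortality temperature

`find_mmt()` scans the cumulative (lag-summed) log relative risk on a
percentile grid and takes the argmin as the reference percentile $x_0$.
Numerical choices: grid step 0.1 percentile; search bounds 1--99 by
default, because the spline variance grows at the extreme percentiles and
an unbounded argmin can stick to a noisy boundary; ties resolve to the
lowest percentile. Because recentring shifts the whole curve by a
constant, the located minimum does not depend on any centring used during
fitting. The MMT is a property of the fitted model: it is held fixed when
the counterfactual scenario is evaluated.

# Stage two: attribution

## Backward attributable fractions

For each case day $t$ the attributable fraction is

$$\mathrm{AF}_{x,t} = 1 - \exp\Big(-\sum_{l=l_0}^{L}
  \beta_{x_{t-l},\,l}\Big),$$

where $\beta_{x,l}$ is the lag-$l$ log relative risk of exposure $x$
versus the reference $x_0$, read off the cross-basis contrast at that
single lag. Attributable fractions are summed over cases to give the
attributable number (AN); negative contributions (protective days) are
retained, since truncating them would bias the AN upward. The same case
set is evaluated under the factual and the counterfactual exposure
series; only the exposures change, and the climate-change excess is the
component-wise difference (`climate_excess()`). With zero warming the two
series are identical and every excess is *exactly* zero -- a pipeline
invariant the acceptance tests check literally.

## Heat, cold, and severity ranges

Burdens are split into heat ($x > x_0$) and cold ($x \le x_0$) components
and into six severity ranges cut at the 2.5th, 25th, $x_0$, 75th and
97.5th percentiles (extreme/moderate/mild cold, mild/moderate/extreme
heat). Two restriction conventions are implemented:

* `"case_day"` (default): each case's whole AF is assigned to the
  side/range of its lag-0 (case-day) exposure. This is the convention of
  the standard backward-attribution software in this literature, and it
  makes the decomposition *exactly* additive: bins sum to their side and
  heat + cold = total, by construction.
* `"per_lag"`: lag contributions outside the requested range are zeroed
  inside the exponent. This follows the algebra of the AF formula more
  literally, but because $1-e^{-(a+b)} \ne (1-e^{-a}) + (1-e^{-b})$, it is
  exactly additive only for cases whose lags all fall on one side; for
  mixed cases the signed discrepancy is reported as an attribute
  (`additivity_gap`), never hidden.

Both conventions agree on the total and on all one-sided cases. The
package defaults to `"case_day"` because exact additivity is what the
reported tables assume.

## Rates and uncertainty

Attributable fractions convert to rates per 100,000 live births by
scaling the country's neonatal mortality rate,
$\mathrm{AR} = m_{\mathrm{neonat}} \cdot \mathrm{AF}_{CC}$; for
day-of-birth deaths the rate is first multiplied by the country's share of
neonatal deaths occurring on day 0 (`attributable_rate()`).

Uncertainty is propagated by Monte Carlo (`monte_carlo_ui()`): coefficient
vectors are drawn from $\mathcal{N}(\hat\beta, \hat V)$, the factual and
counterfactual burdens and their difference are recomputed for every draw,
draws are pooled across temperature datasets with equal weight, the point
estimate is the pooled mean and the 95% uncertainty interval the empirical
2.5th/97.5th percentiles. The default is 10,000 draws; the test suite
uses 1,000 for speed, which widens Monte Carlo noise on the interval
endpoints by roughly a factor of three but leaves coverage properties
intact. A covariance matrix failing positive semi-definiteness beyond a
$10^{-10}$ relative tolerance is an error; tiny negative eigenvalues
within it are clipped.

# The synthetic world

Because the real inputs (registration-gated survey microdata, multi-GB
reanalysis grids) cannot be bundled, `simulate_world()` generates a
complete synthetic study with a *known* answer:

* **Temperatures.** Per location, the counterfactual is a seasonal cosine
  plus AR(1) weather noise (defaults: means 15--28 degC across locations,
  amplitudes 10--3 degC, noise SD 2.5 degC, lag-1 autocorrelation 0.7);
  the factual adds a linear ramp rising to `warming` degC (default 0.9,
  the warming contrast of the emulated 2001--2019 study window) at the
  period end. Generating the counterfactual first and adding the ramp
  makes the pair share weather variability and preserves the within-day
  rank timing of warm and cold spells, mirroring how real counterfactual
  datasets are constructed by rank-preserving detrending. The mean
  factual-counterfactual difference of a linear ramp is half the total
  (0.45 degC), which the tests verify in closed form.
* **Deaths.** Each child's survival over days of life 0--28 is simulated
  day by day with hazard $h_0 \exp\{\sum_l w_l f(\mathrm{pct}_{t-l})\}$,
  where $f$ is a known U-shaped log-RR curve with its minimum at the 50th
  percentile and $w$ are lag weights summing to one (default 0.5/0.3/0.2).
  The default $h_0 = 0.0012$ gives a 28-day cumulative mortality near
  3.5%, typical of the high-mortality settings the design targets. A
  hazard that would exceed probability 1 on any day is an error, not a
  clamp.
* **The true curve.** By default $f$ is built *inside the span of the
  fitted exposure spline* (knot at 20, boundary 0/100), scaled to log-RR
  0.35 at the cold end (the implied heat end is 0.19, reproducing the
  typical asymmetry in which neonatal cold risk exceeds heat risk).
  Because the lag basis spans the lag-weight vector and the leftover
  separable term is set-constant (hence invisible to the conditional
  likelihood), the fitted model is *exactly well specified* under the
  default truth: recovery tests measure estimation error, not
  spline-approximation error. An asymmetric piecewise-quadratic truth is
  available (`true_exposure_response("quadratic")`) for deliberate
  misspecification studies, and a flat variant of it underpins the
  constant-hazard closed-form test.
* **Recall.** Interview dates are set to the day after the period ends,
  so the `recall_years` restriction (default 15) is exercised purely
  through `select_deaths()`.

What the generator does **not** emulate: spatial correlation between
locations, interannual climate modes, survey sampling weights, reporting
omissions or misclassified stillbirths, or GPS displacement. Passing
recovery tests therefore demonstrate that the estimator chain is correct
under its own assumptions -- not that those assumptions hold in any real
survey.

# Problem sizes used by the checks

The recovery check runs 10 locations at 136,000 births each, which yields
roughly 40,000 analysed deaths after recall restriction -- enough for the
estimated MMT to land within ±5 percentile points of the truth and for
the pointwise 95% CI to cover the true curve over the 1--99 grid. The
Monte Carlo coverage check uses 50 replicates of a 2-location world with
1,000 draws each; the end-to-end demo uses 3 locations at 8,000 births.
These sizes are the package's own choices balancing statistical
resolution against a test suite that runs in about a minute.

# Known limitations

* The pooled design estimates one exposure-response shape for all
  locations; only the location of the minimum adapts through the
  percentile scale. Real heterogeneity in curve shape is not modelled.
* Percentile exposure compresses absolute extremes: two locations' 99th
  percentiles may differ by many degrees, which can understate extreme
  heat effects.
* The conditional-likelihood fit assumes one case per set; this is
  guaranteed here (each death forms its own set) but means within-set
  multi-case ties never arise and no Efron/Breslow approximation is
  needed or provided.
* Monte Carlo intervals propagate coefficient uncertainty only; exposure
  measurement error and percentile-map estimation error are not in the
  intervals (dataset-to-dataset spread is, through pooling).
* The excess burden quantifies the impact of the warming trend, whatever
  its cause; it does not separate anthropogenic forcing from natural
  variability.
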