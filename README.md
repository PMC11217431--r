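# neonatclim

Climate-change attribution of temperature-related neonatal mortality.

Exposure to both high and low ambient temperatures raises the risk of
death in the first 28 days of life, and the long-term warming trend has
been shifting that balance: more heat-related deaths, fewer cold-related
ones. `neonatclim` is an R implementation of the two-stage epidemiological
pipeline used to quantify this, aimed at environmental epidemiologists and
climate-health researchers working with georeferenced birth-history data
(e.g. household-survey birth recodes) and gridded daily temperature
products with factual/counterfactual scenario pairs.

## The method

**Stage one — exposure-response.** Daily mean temperatures are converted
to location-specific percentiles (Hazen convention), so populations in
different climates can be pooled on one exposure scale. Each death day is
matched to the other same-weekday days of its calendar month and year
(time-stratified case-crossover; 3–4 controls per case), and a distributed
lag non-linear model — a cross-basis of natural cubic splines in exposure
percentile (1 knot at the 20th percentile) and in lag (0–2 days, 1 knot at
equally spaced log-lags) — is fitted by maximising the exact conditional
logistic likelihood. The reference percentile `x0` (minimum-mortality
temperature, MMT) is the argmin of the cumulative relative-risk curve.

**Stage two — attribution.** For each case day `t`, the backward
attributable fraction

    AF(x, t) = 1 − exp( − Σ_{l = l0..L} β[x(t−l), l] )

sums lag-specific log relative risks versus `x0`. Summing AFs over cases
gives attributable numbers, split into heat/cold and six severity ranges
(cut at the 2.5th, 25th, MMT, 75th and 97.5th percentiles). The same
cases are re-evaluated under a counterfactual (detrended) temperature
series; the factual − counterfactual difference is the climate-change
excess, `AF_CC`, and rates follow as `AR = m_neonat · AF_CC`. Uncertainty
comes from Monte Carlo draws of the coefficients,
`β ~ MVN(β̂, V̂)`, pooled across temperature datasets (95% empirical
intervals).

Because the real inputs are registration-gated (survey microdata) or
bulky (0.5° reanalysis grids), the package ships a synthetic-world
generator — seasonal AR(1) climates, an additive warming ramp (default
0.9 °C over 2001–2019), and deaths simulated from a known U-shaped
exposure-lag-response surface — so the whole pipeline is testable and
demonstrable offline, with ground truth available for recovery checks.

## Worked example

```r
library(neonatclim)

cfg   <- world_config(n_locations = 6, births_per_location = 60000, seed = 1)
world <- simulate_world(cfg)
#> <synthetic_world> 6 locations, 360000 births, 13247 neonatal deaths

deaths <- select_deaths(world$records, "neonatal", recall_years = 15)  # 10417 deaths

# percentile series (factual reference) for both scenarios
pct_f <- do.call(rbind, lapply(world$series, function(p)
  map_series(fit_percentile_map(p$factual), p$factual)))
pct_c <- do.call(rbind, lapply(world$series, function(p)
  map_series(fit_percentile_map(p$factual), p$counterfactual)))

sets  <- build_matched_sets(deaths, pct_f)
model <- fit_exposure_response(sets)
#> <exposure_response_model> 6 coefficients, MMT percentile 52.1, AIC 30740.29

bf <- scenario_burden(model, deaths, pct_f, "factual")
bc <- scenario_burden(model, deaths, pct_c, "counterfactual")
climate_excess(bf, bc)
#>  component an_factual an_counterfactual an_excess af_excess share_of_factual
#>      total     1016.8            1069.1    -52.31 -0.005022         -0.05145
#>       heat      318.0             269.8     48.23  0.004629          0.15164
#>       cold      698.8             799.3   -100.54 -0.009651         -0.14387
#>  ...
```

Reading the output: the estimated MMT (52.1) recovers the true optimum of
the simulated world (the 50th percentile). In the factual scenario 9.8%
of the 10,417 analysed deaths are associated with non-optimal
temperatures — 6.7% with cold, 3.1% with heat, reflecting the asymmetric
U-curve that generated the data. Differencing against the counterfactual:
the 0.9 °C warming added 48 heat-related deaths (15.2% of the factual
heat burden is attributable to climate change) and averted 101
cold-related deaths (−14.4%). Monte Carlo intervals on the excess:

```r
xf <- exposure_matrix(deaths, pct_f, model$spec$lag)
xc <- exposure_matrix(deaths, pct_c, model$spec$lag)
monte_carlo_ui(model, list(factual = xf, counterfactual = xc),
               n_draws = 1000, seed = 2)
#>     quantity     an  an_lo an_hi       af    af_lo    af_hi
#>  excess.heat   47.8   16.4  79.2  0.00459  0.00157  0.00760
#>  excess.cold -100.5 -129.2 -71.0 -0.00965 -0.01240 -0.00681
```

Both intervals exclude zero with the expected signs. `run_pipeline()`
wraps all of the above (plus AIC knot selection and CSV/JSON artifacts)
under a single YAML/list configuration, and
`inst/cli/neonatclim.R` exposes it as a command-line entry point.

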