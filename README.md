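# riacd

Recurrence-interval analysis with (spatial) autoregressive conditional
duration models for extreme events in hourly monitoring series.

## What problem this solves

Given hourly concentration records from a network of air-quality monitoring
stations, when will the *next* extreme-pollution event arrive?  `riacd`
answers this by modelling the waiting times (recurrence intervals) between
hours on which the diurnally adjusted series exceeds a high threshold
*q*.  It is aimed at researchers working on extreme-event statistics of
environmental time series, and at anyone who needs a tested reference
implementation of duration models with a spatial coupling term.

The workflow:

1. **Adjust** — remove the 24-hour cycle by dividing each value by the
   across-day average at the same hour of day
   (`diurnal_adjust()`), giving a dimensionless series `x` with mean ≈ 1.
2. **Extract** — recurrence intervals `d_{q,s}` between consecutive hours
   with `x > q` (`extract_recurrence()`), plus temporal-structure scans
   (`ar_max_significant_lag()`, `hurst_exponent()`).
3. **Review spatially** — at each interval completion, look up the
   neighbour's most recently completed interval at the same threshold
   (`spatially_reviewed()`); neighbours come from a haversine distance
   matrix over the station registry (`interstation_distances()`).
4. **Model** — the ACD recursion
   `d_s = psi_s * eps_s`,
   `psi_s = omega + sum_u alpha_u d_{s-u} + sum_v beta_v psi_{s-v}
    [+ sum_{j,k} gamma_{j,k} w_{ij} d^{(ij)}_{s-k}]`,
   with unit-mean exponential or Weibull (shape `k` in (0,1]) innovations.
   Fitting is by conditional maximum likelihood (`fit_acd()`) with
   Newey–West HAC standard errors and a Ljung–Box residual test.  Under
   stationarity the expected interval is
   `mu = omega / (1 - alpha - beta)` (`stationary_mean()`, with closed
   forms for coupled station pairs).
5. **Forecast** — one- and multi-step forecasts of the next interval(s)
   (`one_step_forecast()`, `multi_step_forecast()`) and rolling
   out-of-sample evaluation with breakpoint error tables
   (`rolling_forecast()`, `summarize_errors()`).

Synthetic generators (`simulate_acd()`, `simulate_coupled_sacd()`,
`simulate_gaussian_pair()`, `simulate_network()`) make every stage testable
without any external data.  `run_pipeline()` orchestrates the whole chain
over a station network and writes CSV reports; a thin command-line wrapper
lives at `inst/cli/riacd.R`.

## Worked example

Two synthetic stations, threshold `q = 2` on the adjusted scale, spatial
model with the neighbour's reviewed intervals:

```r
library(riacd)
net <- simulate_network(n_stations = 2, n_hours = 20000, seed = 42)
adj <- diurnal_adjust(net$series[["1.PM2.5"]])
rec <- extract_recurrence(adj, q = 2)
rec
#> <recurrence_series> q = 2.00: 2353 events over 20000 hours, <d> = 8.50 h

nb   <- extract_recurrence(diurnal_adjust(net$series[["2.PM2.5"]]), q = 2)
pair <- spatially_reviewed(rec, nb)
fit  <- fit_acd(rec$durations, d_review = pair,
                order = sacd_order(1, 1, 1, neighbours = "2"))
fit
#> RIA-SACD(1,1,1) fit, exponential innovations, N = 2352
#>          estimate     se sig
#> omega      0.0177 0.0808
#> alpha1     0.0000 0.0110
#> beta1      0.9945 0.0175 ***
#> gamma1.1   0.0034 0.0034
#> logLik = -7382.060; Ljung-Box Q(10) = 7.65 (p = 0.66)

one_step_forecast(fit)
#> 9.06
```

Reading the output: events recur every 8.5 hours on average; the fitted
conditional-duration process is strongly persistent (`beta1 = 0.99`,
significant at the 1% level, stars from Newey–West z-statistics), while this
particular synthetic pair carries no significant spatial signal
(`gamma1.1` insignificant — the generator's cross-correlation of 0.8 sits
near the edge of where reviewed-interval correlation emerges).  The
insignificant Ljung–Box statistic says the residuals are serially
uncorrelated, i.e. the dynamics were captured.  The model expects the next
interval in about 9.1 hours.  A rolling 30-interval out-of-sample test on
the same durations gives

```r
rolling_forecast(rec$durations, d_review = pair$reviewed,
                 order = sacd_order(1, 1, 1, neighbours = "2"),
                 holdout = 30, restarts = 1)$summary
#>   p_ae_lt_1 p_ae_lt_6 p_ae_lt_12 p_ae_lt_24 p_ae_lt_48 p_ae_lt_96 avg_ae   rmse
#>       0.1     0.633      0.967      0.967      0.967          1  5.974 11.518
```

i.e. 97% of one-step forecasts land within 12 hours of the realized
interval, with a mean absolute error of about 6 hours.

## Documentation

The methods vignette (`vignettes/recurrence-acd-methods.Rmd`) documents the
model and its assumptions, estimation and numerical conventions, what the
synthetic generators do and do not emulate, and known limitations.
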