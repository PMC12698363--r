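# bathmort

Two-stage time-series analysis of daily bath-related drowning mortality.

In Japan, drowning deaths in home bathtubs peak sharply in winter, and a
large share of that seasonality is attributable to outdoor temperature
acting through bathing behaviour and thermoregulatory stress. `bathmort`
implements the full analysis pipeline used to quantify this at national
scale, for epidemiologists and biostatisticians working with daily count
panels across regions:

1. **Region-level quasi-Poisson regression.** For region *i*, daily deaths
   are modelled as
   `log E[Y_t] = log P_t + alpha + s(doy_t; 4 df) + cb(x_t, ..., x_{t-21}) + covariates`,
   with population offset `P_t`, a cyclic day-of-year spline `s` (periodic
   cubic B-splines on a 1–365 grid, 4 df), and a distributed-lag nonlinear
   (DLNM) cross-basis `cb` combining a natural cubic spline of mean outdoor
   temperature (knots at the pooled 10th/75th/90th percentiles) with a
   natural cubic spline over lags 0–21 days (intercept plus log-spaced
   knots), centred at the pooled median temperature. The dispersion
   parameter is estimated from Pearson residuals and scales all covariances.
2. **Multivariate meta-analytic pooling.** Coefficient blocks (seasonal
   spline, cross-basis, or scalar day-type contrasts) are combined across
   regions by multivariate random-effects meta-analysis (REML over the
   Cholesky factor of the between-region covariance, with method-of-moments
   and fixed-effects alternatives).
3. **Seasonality summaries.** The pooled seasonal curve yields peak/trough
   timings, the peak-to-trough ratio (PTR) with Wald CIs, and the seasonal
   attributable fraction `AF = 100 * sum_t n_t (1 - exp(-logRR(doy_t))) / sum_t n_t`
   — the share of deaths avoidable at trough-level risk — with Monte Carlo
   empirical CIs from multivariate-normal coefficient draws (the trough is
   re-located within every draw). Running the model with and without the
   cross-basis decomposes the seasonal AF into its temperature-driven and
   residual parts. Period-stratified AFs (with a prop-aged-65+ covariate)
   are supported.
4. **Temperature response.** The pooled cross-basis gives the overall
   cumulative exposure–response curve, lag-specific slices and the full
   temperature-by-lag RR surface.
5. **Day-type relative risks.** Holidays, New Year's Day/Eve,
   Coming-of-Age Day and day-of-week (Friday reference), unadjusted and
   adjusted (seasonal spline + cross-basis + day-of-week-by-year strata or
   holiday/year dummies), pooled univariately across regions.
6. **Projections.** The seasonality model extended with prop-65+ and linear
   calendar year projects expected daily deaths over 2020–2069 under
   crossed temperature pathways and population trajectories, aggregated by
   decade and expressed relative to a baseline cell.

A seeded synthetic-data generator (`sim_config()`, `simulate_panels()`,
`simulate_scenarios()`) produces multi-region panels with *known*
seasonal, lagged-cold, and day-type effects, so every stage is testable by
parameter recovery against closed-form ground truth.

## Worked example

```r
library(bathmort)

cfg <- sim_config(n_regions = 5, date_range = c("2001-01-01", "2008-12-31"),
                  seed = 1, baseline_rate = 6e-7)
panels <- simulate_panels(cfg)

analyze_seasonality(panels, n_sim = 2000, seed = 1)
#> seasonality summary (unadjusted for temperature):
#>   peak day 35 (eCI 28-40), trough day 167 (eCI 162-177)
#>   peak-to-trough ratio 2.39 (95% CI 2.29-2.50)
#>   attributable fraction 33.9% (95% eCI 32.0-36.0)

analyze_seasonality(panels, cb = TRUE, n_sim = 2000, seed = 1)
#> seasonality summary (adjusted for temperature):
#>   peak day 1 (eCI 1-365), trough day 158 (eCI 133-203)
#>   peak-to-trough ratio 1.28 (95% CI 1.17-1.39)
#>   attributable fraction 12.8% (95% eCI 9.2-18.2)
#>   note: timing eCI spans more than half the year (multimodal draws)

analyze_temperature(panels)
#> pooled cumulative temperature association (reference 16.1 C):
#>   RR 2.56 (2.24-2.92) at -1 C; RR 0.84 (0.68-1.05) at 33 C
```

Reading the output: mortality peaks in early February and troughs in June;
about a third of all simulated deaths are attributable to seasonality, and
adjusting for outdoor temperature removes roughly two thirds of that
seasonal AF (33.9% to 12.8%), leaving a flat residual curve whose peak
timing is barely identified (the multimodality note). The cumulative curve
shows the lagged cold effect: a 2.5-fold risk near -1 °C relative to the
median temperature. The generator's true unadjusted PTR for this
configuration is 2.29, inside the estimation error of the 2.39 estimate.

Real data enter through `read_panel()` (long-format CSVs of daily deaths,
daily mean temperature, yearly population/prop-65+, and a holiday
calendar), with `impute_temperature()` applying the
same-calendar-date-in-earlier-years imputation rule. The one-shot
`run_pipeline()` (or `exec/bathmort run-all --config cfg.yaml`) executes
simulate → fit → pool → summarise → project and writes all CSV outputs with
provenance headers.

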