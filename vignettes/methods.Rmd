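---
title: "Methods: seasonality, temperature lags and projections for daily bath-related drowning mortality"
author: "bathmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonality, temperature lags and projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the two-stage design

Daily counts of bathtub drowning deaths in a country like Japan are sparse
at the region level (often 0–3 deaths per prefecture-day), strongly
seasonal, and sensitive to outdoor temperature with effects distributed
over days to weeks. The package follows the standard two-stage design of
environmental time-series epidemiology: stage one fits a separate
quasi-Poisson regression in each region, so that region-specific climate
and baseline differences never contaminate each other; stage two combines
the region coefficient vectors — not the data — by multivariate
random-effects meta-analysis, yielding a national average curve with
honest between-region heterogeneity.

The stage-one model for daily deaths $Y_t$ in one region is

$$\log E[Y_t] = \log P_t + \alpha + s(\mathrm{doy}_t)
  + cb(x_t, \dots, x_{t-21}) + \gamma^\top z_t,$$

where $P_t$ is the population that year (offset, turning counts into
rates), $s$ a cyclic day-of-year spline, $cb$ the temperature cross-basis,
and $z_t$ optional calendar covariates. Counts are assumed conditionally
independent Poisson with a multiplicative dispersion $\phi$ estimated from
Pearson residuals (`sum(r_P^2)/df`); point estimates are the Poisson MLE
and $\phi$ scales all covariances. No floor is applied to $\phi$ by
default — it is reported as estimated (a `floor_dispersion` switch
exists). All intervals are Wald-type, consistent with two-stage DLNM
practice.

## The cyclic seasonal basis

Day-of-year runs on a fixed 1–365 grid. February 29 is mapped to day 59
(the same index as February 28) so the cycle length is exactly 365 and the
leap-day rows are retained in fitting; a 366-point cycle would subtly
distort the period in all common years. The basis itself is a periodic
cubic B-spline design with `df + 1` evenly spaced knot intervals over the
cycle; periodic B-splines form a partition of unity, so the first column
is dropped, leaving `df` columns of full rank alongside the model
intercept. The default `df = 4` resolves a single annual peak and trough
with some asymmetry while remaining estimable in regions with few deaths;
values below 3 are rejected. Basis values and two derivatives are
continuous across the December–January wrap, which matters because the
mortality peak falls near the year boundary.

## The temperature cross-basis

The distributed-lag nonlinear model represents the exposure–lag–response
surface as a tensor product of two marginal spline bases:

* exposure: natural cubic spline of daily mean temperature (°C), internal
  knots at the pooled 10th/75th/90th percentiles, boundary knots at the
  pooled range — knots concentrated where cold effects live;
* lag: natural cubic spline over lags 0–21 days with an intercept and
  three internal knots equally spaced on the log-lag scale, so early lags
  (where effects change fastest) get most of the flexibility.

Row $t$ of the cross-basis is
$Z_{t,(j,k)} = \sum_{l=0}^{21} \{v_j(x_{t-l}) - v_j(\mathrm{ref})\}\,c_k(l)$,
centred at the reference temperature so a constant history at the
reference maps to log-RR 0 by construction. The reference defaults to the
pooled median across regions, and a *common* spec (pooled knots, pooled
reference) is used for all regions so their coefficient vectors are
poolable; per-region curves can be re-centred at prediction time without
refitting. The first 21 days of each region's window lack a complete lag
history: when pre-period temperatures are supplied they are used, and any
remaining incomplete rows are dropped from fitting. Reported curves are
the cumulative exposure–response (lag effects summed), lag slices
(defaults 0, 2, 7, 10), and the full temperature-by-lag surface, on a 1 °C
grid spanning the pooled 1st–99th percentiles; grid points beyond the
spline support trigger an extrapolation warning, not an error. These
defaults are explicit conventions of the temperature–mortality DLNM
literature, not claims about any particular dataset, and every one of them
is overridable in `cb_spec()`.

## Pooling

`pool_estimates()` implements generalised-least-squares pooling with
weights $(V_i + \Psi)^{-1}$. $\Psi$ (between-region covariance) is zero
for fixed effects; the moment estimator truncates the between-region
sample covariance minus the mean within-region covariance to the nearest
positive-semidefinite matrix; REML (the default) maximises the restricted
likelihood over the Cholesky factor of $\Psi$, started at the moment
estimate, falling back to it if the optimiser fails. Intercepts are never
pooled — only curve-shape blocks or named scalar contrasts — because
baselines are region idiosyncrasies. Seasonal and cross-basis blocks are
pooled *separately*: a joint 24-dimensional pooling across a few dozen
regions would leave $\Psi$ essentially unidentified, and the package warns
whenever the block dimension exceeds the number of regions. No
meta-regression on region-level covariates is offered.

## Seasonality summaries and Monte Carlo eCIs

The pooled seasonal curve is evaluated on the integer day grid and
referenced at its trough. The peak-to-trough ratio is
$\exp\{c^\top\theta\}$ with contrast $c = b(\mathrm{peak}) -
b(\mathrm{trough})$ and a Wald CI from the pooled covariance. The
attributable fraction weights each day's excess risk by the *observed*
deaths (the backward attributable-number convention; a `weights` argument
allows fitted-count weights instead):
$AF = 100\sum_t n_t\{1 - e^{-\mathrm{logRR}(\mathrm{doy}_t)}\}/\sum_t
n_t$, so $AF \in [0, 100)$ always.

Empirical CIs come from 5000 multivariate-normal draws of the pooled
coefficients (seed-reproducible; `MASS::mvrnorm`). Crucially the trough is
re-located within every draw before the statistic is recomputed — this is
what makes the timing eCIs meaningful, and it is also why they can behave
oddly: when the adjusted curve is nearly flat, the argmax/argmin
distribution across draws becomes multimodal and raw 2.5/97.5 percentiles
may span most of the year. The summary reports the raw percentiles and
sets a `multimodal` flag when a timing interval exceeds half a year,
rather than pretending to a tighter construction. Timing intervals are
integer days (percentile type 1); a draw failure rate above 1% aborts.
Period-stratified AFs (defaults 1995–2003, 2004–2012, 2013–2020) refit
within periods with the proportion aged 65+ as a covariate, so that
age-structure drift does not masquerade as seasonality change.

## Day-type models

Holiday-class membership is resolved with named-day precedence: New Year's
Day and Coming-of-Age Day carry their own indicators and are removed from
the generic holiday indicator, and New Year's Eve — not a statutory
holiday — is only ever its own indicator. This coding makes all four rows
of the day-type table estimable in a single model without double-counting;
a one-vs-rest alternative can be had by building designs directly. The
adjusted holiday model controls temporal confounding with *full*
day-of-week-by-year strata (no main effects outside the interaction, first
cell as reference); the adjusted day-of-week model uses holiday and year
dummies with Friday as the day-of-week reference. Both adjusted variants
include the seasonal spline and the cross-basis. Per-region log-RRs are
pooled univariately with two-sided Wald p-values. Coming-of-Age Day's
statutory date change (January 15 through 1999, second Monday of January
afterwards) is taken from the holiday calendar file, not hard-coded.

## Projections

The projection model adds the proportion aged 65+ (linear) and calendar
year to the seasonality model. Year enters *linearly*, centred at the
first fitted year: a future year cannot be represented by historical year
dummies, and a linear term is the only specification that extrapolates;
`freeze_year = TRUE` zeroes it for a pure demographic-plus-climate
projection. Projections evaluate expected counts only (no Poisson noise;
a `stochastic` switch adds it), with scenario temperature through the
cross-basis, scenario prop-65+/year, and scenario population in the
offset; daily values are summed into decades with no smoothing across
boundaries, expressed per capita against the decade's mean population, and
as ratios to a baseline cell (first decade, intermediate population,
middle temperature pathway), which is exactly 1 by construction. The
package does not claim numeric agreement with any published projection
figure — those depend on restricted inputs — only the structural
properties tested here (exact offset linearity, baseline ratio, monotone
response to warming under a fitted cold effect).

## The synthetic-data generator

`sim_config()` defines the ground truth the test suite recovers. Defaults
emulate the observed national study conditions: 47 regions over
1995–2020; temperature as an annual cosine (mean 16 °C, amplitude
10.5 °C, peak day 219) plus AR(1) anomalies (rho 0.8, innovation SD
2.3 °C, stationary SD ≈ 3.8 °C); a direct seasonal component with
amplitude `log(1.34)/2` peaking on day 9 (so the temperature-adjusted PTR
target is 1.34); a cold effect of 0.058 log-RR per °C below 15 °C spread
over lags 0–21 with geometric weights (ratio 0.75, so the lag-10 weight is
about 6% of lag 0 — the effect has largely disappeared by lag 10), which
makes the true cumulative RR at 0 °C versus the ~16 °C median about 2.4;
day-type multipliers Sunday 1.16, Monday 1.05, Saturday 1.04, holiday
1.12, New Year's Day 1.72, New Year's Eve 1.63; and a baseline rate of
4e-8 deaths/person/day with 2.7 million persons per region, giving
national totals of order 1e5 deaths over 26 years. Counts are Poisson by
default so the quasi-Poisson dispersion estimate has the known target 1
(a negative-binomial switch exists for overdispersion studies). The
ageing trajectory starts at 14.5% aged 65+ with an initial slope of
0.55 points/year and saturates exponentially towards 40% — a realistic
deceleration which also keeps prop-65+ from being exactly collinear with
the linear year term of the projection model. Scenario pathways share one
realisation of the weather noise and differ only in their linear warming
trends, so cross-pathway contrasts isolate the warming signal.

The generator's closed-form truths drive the recovery tests: the direct
seasonal PTR is exactly $e^{2A}$; the expected temperature-mediated
seasonal component uses the rectified-Gaussian mean
$E[\max(0, c - T)] = (c-m)\Phi\!\left(\frac{c-m}{s}\right) +
s\,\phi\!\left(\frac{c-m}{s}\right)$ summed over lag weights; the true AF
follows by evaluating the AF formula on the true curve.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: spatial correlation between regions,
climate-model bias structure, non-stationary seasonal amplitude,
reporting artefacts (e.g. date-of-death versus date-of-incident
mismatch), and municipal heterogeneity within regions. Its holiday
calendar is a synthetic approximation of the statutory one (fixed-date
approximations, no substitute-holiday or equinox rules).

## Numerical choices

IRLS convergence is 1e-8 on the relative deviance change with a 100
iteration cap; rank deficiency is detected by QR and reported with the
offending columns. Covariances are reconstructed from the QR factor with
pivot-aware ordering. PSD truncation (for moment estimates of $\Psi$ and
for Monte Carlo draw covariances) clamps negative eigenvalues at zero.
Ties in peak/trough location break to the earliest day. Degenerate inputs
error early: all-zero responses, constant prop-65+, missing scenario
days, unimputable temperatures (no same-calendar-date value in any
earlier year — the first year and February 29 without a prior leap year
can never be imputed), duplicate or gapped dates.

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations as the
package's own choice of informative-but-small designs: unit tests use 1–6
regions over 2–12 years with baseline rates scaled up so counts stay
informative; the headline recovery runs use 10 regions over 26 years with
expected totals of order 1e5 deaths (PTR within 10% relative error and AF
within 3 points of generator truth), 200 reduced single-region
replications for the Sunday-RR coverage check, and 5000 Monte Carlo draws
for interval comparisons.

## Known limitations

REML over a full Cholesky factor scales poorly beyond a few dozen
coefficient dimensions and is weakly identified when the block dimension
exceeds the region count (a warning is issued, and the moment estimator is
the pragmatic fallback). The AF convention uses
observed-death weights; fitted-weight AFs differ slightly in small
samples. Projections extrapolate a linear year effect and the fitted
cross-basis beyond the support of the fitting data when scenarios warm
strongly; extreme-grid RRs are flagged as extrapolation. The package
models all-ages counts; age/sex stratification of deaths is out of scope,
as are heat-wave added effects, humidity, and attribution split into
separate cold/heat components.
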