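#' Simulation configuration for the synthetic-data generator
#'
#' Defines the ground truth of the synthetic multi-region daily panel:
#' a log-linear daily death rate combining a direct cyclic seasonal term, a
#' lagged cold-temperature effect (piecewise-linear below a threshold,
#' distributed over lags by fixed weights), day-of-week and special-day
#' multipliers, and an offset population with an ageing trajectory.
#' Temperatures follow a seasonal cosine plus AR(1) noise.
#'
#' Defaults emulate the observed study conditions for Japan, 47 prefectures,
#' 1995-2020: a direct seasonal amplitude matching a temperature-adjusted
#' peak-to-trough ratio near 1.34 peaking in early January; a cold slope of
#' 0.058 log-RR per degree C below 15 degrees C (cumulative RR about 2.4 at
#' 0 C versus the median); geometric lag weights over lags 0-21 decaying so
#' the effect has largely disappeared by lag 10; day-type multipliers 1.16
#' (Sunday), 1.12 (holiday), 1.72 (New Year's Day), 1.63 (New Year's Eve);
#' and a baseline rate scaled so national totals are of the order of 1e5
#' deaths over 26 years.
#'
#' @param n_regions number of regions (default 47).
#' @param date_range character or Date length-2, inclusive panel window.
#' @param seed integer master seed; all randomness derives from it.
#' @param baseline_rate deaths per person per day at reference conditions.
#' @param seasonal_amplitude_logRR half the peak-to-trough log range of the
#'   direct (non-temperature) seasonal component.
#' @param seasonal_peak_doy day-of-year of the direct seasonal peak.
#' @param temp_mean_C,temp_seasonal_amplitude_C,temp_peak_doy annual mean,
#'   cosine amplitude and peak day of the temperature cycle.
#' @param temp_ar1_rho,temp_noise_sd AR(1) parameter and innovation SD of
#'   the temperature anomaly (degrees C).
#' @param cold_slope_logRR_per_degC log-RR per degree C below the threshold
#'   (cumulative over lags).
#' @param cold_threshold_C temperature below which the cold effect applies.
#' @param lag_weights non-negative weights over lags `0..L`, summing to 1.
#' @param dow_logRR length-7 log-RR vector, Monday first, Friday must be 0
#'   (reference).
#' @param holiday_logRR,nyd_logRR,nye_logRR log-RRs for generic holidays,
#'   New Year's Day and New Year's Eve (named-day effects replace, not
#'   stack on, the generic holiday effect).
#' @param population_per_region persons per region (constant over time).
#' @param prop65_start,prop65_trend_per_year starting proportion aged 65+
#'   and its initial yearly increment; the trajectory saturates towards
#'   `prop65_asymptote` (exponential approach with that initial slope).
#' @param prop65_asymptote long-run ceiling of the ageing trajectory.
#' @param prop65_logRR log-RR per unit of prop65 (default 0: ageing affects
#'   the offset structure only, not the rate).
#' @param family `"poisson"` (dispersion 1, the default, so the
#'   quasi-Poisson dispersion estimate has a known target) or `"nbinom"`.
#' @param nb_size negative-binomial size when `family = "nbinom"`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_regions = 47,
                       date_range = c("1995-01-01", "2020-12-31"),
                       seed = 1,
                       baseline_rate = 4e-8,
                       seasonal_amplitude_logRR = log(1.34) / 2,
                       seasonal_peak_doy = 9,
                       temp_mean_C = 16,
                       temp_seasonal_amplitude_C = 10.5,
                       temp_peak_doy = 219,
                       temp_ar1_rho = 0.8,
                       temp_noise_sd = 2.3,
                       cold_slope_logRR_per_degC = 0.058,
                       cold_threshold_C = 15,
                       lag_weights = geometric_lag_weights(21, 0.75),
                       dow_logRR = log(c(1.05, 1, 1.02, 1.01, 1, 1.04, 1.16)),
                       holiday_logRR = log(1.12),
                       nyd_logRR = log(1.72),
                       nye_logRR = log(1.63),
                       population_per_region = 2.7e6,
                       prop65_start = 0.145,
                       prop65_trend_per_year = 0.0055,
                       prop65_asymptote = 0.40,
                       prop65_logRR = 0,
                       family = c("poisson", "nbinom"),
                       nb_size = 10) {
  family <- match.arg(family)
  stopifnot(length(dow_logRR) == 7, length(date_range) == 2)
  if (any(lag_weights < 0) || abs(sum(lag_weights) - 1) > 1e-12)
    stop("lag_weights must be non-negative and sum to 1")
  if (abs(temp_ar1_rho) >= 1) stop("temp_ar1_rho must be in (-1, 1)")
  cfg <- list(
    n_regions = as.integer(n_regions),
    date_range = as.Date(date_range), seed = as.integer(seed),
    baseline_rate = baseline_rate,
    seasonal_amplitude_logRR = seasonal_amplitude_logRR,
    seasonal_peak_doy = seasonal_peak_doy,
    temp_mean_C = temp_mean_C,
    temp_seasonal_amplitude_C = temp_seasonal_amplitude_C,
    temp_peak_doy = temp_peak_doy,
    temp_ar1_rho = temp_ar1_rho, temp_noise_sd = temp_noise_sd,
    cold_slope_logRR_per_degC = cold_slope_logRR_per_degC,
    cold_threshold_C = cold_threshold_C,
    lag_weights = lag_weights, max_lag = length(lag_weights) - 1L,
    dow_logRR = dow_logRR, holiday_logRR = holiday_logRR,
    nyd_logRR = nyd_logRR, nye_logRR = nye_logRR,
    population_per_region = population_per_region,
    prop65_start = prop65_start,
    prop65_trend_per_year = prop65_trend_per_year,
    prop65_asymptote = prop65_asymptote,
    prop65_logRR = prop65_logRR,
    family = family, nb_size = nb_size)
  class(cfg) <- "sim_config"
  cfg
}

#' Geometric lag-weight profile
#'
#' Weights `ratio^l` over lags `0..max_lag`, normalised to sum to 1.
#'
#' @param max_lag maximum lag.
#' @param ratio decay ratio per lag day.
#' @export
geometric_lag_weights <- function(max_lag = 21, ratio = 0.75) {
  w <- ratio^(0:max_lag)
  w / sum(w)
}

region_seed <- function(cfg, region_index, stream = 0L) {
  (((cfg$seed %% 1000003) * 2017 + region_index * 101 + stream * 7) %%
     2147483647) + 1
}

prop65_at <- function(cfg, year) {
  y0 <- as.integer(format(cfg$date_range[1], "%Y"))
  r <- cfg$prop65_trend_per_year / (cfg$prop65_asymptote - cfg$prop65_start)
  cfg$prop65_asymptote - (cfg$prop65_asymptote - cfg$prop65_start) *
    exp(-r * (year - y0))
}

temp_mean_curve <- function(cfg, doy) {
  cfg$temp_mean_C + cfg$temp_seasonal_amplitude_C *
    cos(2 * pi * (doy - cfg$temp_peak_doy) / 365)
}

#' Simulate a daily temperature series for one region
#'
#' Seasonal cosine plus stationary AR(1) noise, reproducible from the
#' configuration seed and region index. The returned series starts
#' `max_lag` days before the panel window so that the cross-basis has a
#' complete lag history from the first panel day.
#'
#' @param cfg a [sim_config()].
#' @param region_index integer region index (1-based).
#' @return data frame (`date`, `tmean`).
#' @export
simulate_temperature <- function(cfg, region_index = 1) {
  dates <- seq(cfg$date_range[1] - cfg$max_lag, cfg$date_range[2], by = "day")
  n <- length(dates)
  seas <- temp_mean_curve(cfg, doy365(dates))
  noise <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(region_seed(cfg, region_index, 0L))
    e <- stats::rnorm(n, 0, cfg$temp_noise_sd)
    a <- numeric(n)
    s0 <- cfg$temp_noise_sd / sqrt(1 - cfg$temp_ar1_rho^2)
    a[1] <- if (cfg$temp_noise_sd > 0) stats::rnorm(1, 0, s0) else 0
    for (t in seq_len(n)[-1]) a[t] <- cfg$temp_ar1_rho * a[t - 1] + e[t]
    a
  })
  data.frame(date = dates, tmean = seas + noise)
}

cold_exposure <- function(cfg, tmean) pmax(0, cfg$cold_threshold_C - tmean)

#' True log-rate components on a panel's days
#'
#' Evaluates the generator's linear predictor (excluding the Poisson noise)
#' for a region's dates and temperature series; used internally by
#' [simulate_deaths()] and exported so tests can recover ground truth.
#'
#' @param cfg a [sim_config()].
#' @param cal calendar covariates for the panel days.
#' @param tmean_full temperature series covering `max_lag` days before the
#'   first panel day through the last.
#' @return list with components `seasonal`, `cold`, `daytype`, `prop65`
#'   (log-RR vectors) and `log_mu` (full log mean including offset and
#'   baseline).
#' @export
true_linear_predictor <- function(cfg, cal, tmean_full) {
  n <- nrow(cal)
  L <- cfg$max_lag
  stopifnot(length(tmean_full) == n + L)
  cold_all <- cold_exposure(cfg, tmean_full)
  cold <- numeric(n)
  for (l in 0:L)
    cold <- cold + cfg$lag_weights[l + 1] * cold_all[seq_len(n) + L - l]
  cold <- cfg$cold_slope_logRR_per_degC * cold
  seasonal <- cfg$seasonal_amplitude_logRR *
    cos(2 * pi * (cal$doy - cfg$seasonal_peak_doy) / 365)
  daytype <- cfg$dow_logRR[cal$dow]
  special <- cal$is_new_years_day | cal$is_new_years_eve |
    cal$is_coming_of_age_day
  daytype <- daytype + ifelse(cal$is_holiday & !special, cfg$holiday_logRR, 0) +
    ifelse(cal$is_new_years_day, cfg$nyd_logRR, 0) +
    ifelse(cal$is_new_years_eve, cfg$nye_logRR, 0) +
    ifelse(cal$is_coming_of_age_day & !cal$is_new_years_day,
           cfg$holiday_logRR, 0)
  p65 <- prop65_at(cfg, cal$year)
  prop65_term <- cfg$prop65_logRR * p65
  log_mu <- log(cfg$population_per_region) + log(cfg$baseline_rate) +
    seasonal + cold + daytype + prop65_term
  list(seasonal = seasonal, cold = cold, daytype = daytype,
       prop65 = prop65_term, log_mu = log_mu, prop65_value = p65)
}

#' Simulate deaths for one region given its temperature series
#'
#' Draws daily death counts from the configured count distribution with
#' mean `exp(log_mu)` from [true_linear_predictor()] and assembles a
#' [region_panel] whose first `max_lag` temperature days become the panel's
#' `tmean_history`.
#'
#' @param cfg a [sim_config()].
#' @param temp data frame from [simulate_temperature()] for the same region.
#' @param region_index region index (also seeds the count draws).
#' @param holidays holiday calendar; defaults to [make_holiday_calendar()]
#'   over the covered years.
#' @return a [region_panel].
#' @export
simulate_deaths <- function(cfg, temp, region_index = 1, holidays = NULL) {
  in_window <- temp$date >= cfg$date_range[1]
  dates <- temp$date[in_window]
  if (is.null(holidays))
    holidays <- make_holiday_calendar(unique(as.integer(format(temp$date, "%Y"))))
  cal <- calendar_covariates(dates, holidays)
  lp <- true_linear_predictor(cfg, cal, temp$tmean)
  mu <- exp(lp$log_mu)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(region_seed(cfg, region_index, 1L))
  deaths <- if (cfg$family == "poisson") stats::rpois(length(mu), mu) else
    stats::rnbinom(length(mu), size = cfg$nb_size, mu = mu)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  df <- cbind(
    data.frame(region = sprintf("R%02d", region_index),
               deaths = as.integer(deaths), tmean = temp$tmean[in_window],
               population = cfg$population_per_region,
               prop65 = lp$prop65_value),
    cal[setdiff(names(cal), "date")], date = dates)
  history <- data.frame(date = temp$date[!in_window],
                        tmean = temp$tmean[!in_window])
  new_region_panel(df, if (nrow(history) > 0) history else NULL)
}

#' Simulate a full multi-region panel collection
#'
#' @param cfg a [sim_config()].
#' @return named list of [region_panel], one per region; the holiday
#'   calendar used is attached as attribute `holidays`.
#' @export
simulate_panels <- function(cfg) {
  years <- seq(as.integer(format(cfg$date_range[1] - cfg$max_lag, "%Y")),
               as.integer(format(cfg$date_range[2], "%Y")))
  holidays <- make_holiday_calendar(years)
  panels <- lapply(seq_len(cfg$n_regions), function(i)
    simulate_deaths(cfg, simulate_temperature(cfg, i), i, holidays))
  names(panels) <- vapply(panels, function(p) p$region[1], "")
  structure(panels, holidays = holidays)
}

#' Ground-truth seasonal log-RR curve of the generator
#'
#' The expected seasonal pattern implied by the configuration on the integer
#' day-of-year grid, trough-referenced. `component = "direct"` is the cyclic
#' term alone (the target of the temperature-adjusted model);
#' `component = "total"` adds the expected temperature-mediated component,
#' using the closed-form mean of the rectified Gaussian cold exposure
#' `E[max(0, c - T)]` with `T ~ N(mean_curve(doy), stationary sd)` summed
#' over the lag weights.
#'
#' @param cfg a [sim_config()].
#' @param component `"total"` or `"direct"`.
#' @return numeric length-365 trough-referenced log-RR vector.
#' @export
true_seasonal_curve <- function(cfg, component = c("total", "direct")) {
  component <- match.arg(component)
  doy <- 1:365
  curve <- cfg$seasonal_amplitude_logRR *
    cos(2 * pi * (doy - cfg$seasonal_peak_doy) / 365)
  if (component == "total") {
    s <- if (cfg$temp_ar1_rho == 0) cfg$temp_noise_sd else
      cfg$temp_noise_sd / sqrt(1 - cfg$temp_ar1_rho^2)
    m <- temp_mean_curve(cfg, doy)
    e_cold <- if (s > 0) {
      z <- (cfg$cold_threshold_C - m) / s
      (cfg$cold_threshold_C - m) * stats::pnorm(z) + s * stats::dnorm(z)
    } else cold_exposure(cfg, m)
    # expected lag-weighted cold exposure by doy (weights sum to 1; the
    # lag-smearing over the slowly-varying seasonal mean is approximated by
    # the weighted average of the donor days' expectations)
    lagged <- numeric(365)
    for (l in 0:cfg$max_lag) {
      idx <- ((doy - 1 - l) %% 365) + 1
      lagged <- lagged + cfg$lag_weights[l + 1] * e_cold[idx]
    }
    curve <- curve + cfg$cold_slope_logRR_per_degC * lagged
  }
  curve - min(curve)
}

#' Simulate future temperature pathways and population trajectories
#'
#' Builds scenario inputs contiguous with the fitting window: for each
#' temperature pathway, the historical generator continued over the horizon
#' plus a linear warming trend (starting at zero at the horizon start); for
#' each population trajectory, a geometric interpolation of national
#' population from 1 to the configured terminal multiplier and the continued
#' ageing trajectory. Temperature series begin `max_lag` days before the
#' horizon so projections have a complete lag history.
#'
#' @param cfg a [sim_config()].
#' @param horizon_start,horizon_end `Date`-coercible horizon bounds
#'   (defaults 2020-01-01 and 2069-12-31).
#' @param warming_per_decade_C named numeric vector, degrees C per decade
#'   per pathway.
#' @param population_multipliers named numeric vector of terminal national
#'   population multipliers per trajectory.
#' @return list with `temperature` (data frame `pathway, date, tmean_c`) and
#'   `population` (data frame `trajectory, year, population, prop65`).
#' @export
simulate_scenarios <- function(cfg,
                               horizon_start = "2020-01-01",
                               horizon_end = "2069-12-31",
                               warming_per_decade_C = c(ssp126 = 0.10,
                                                        ssp245 = 0.25,
                                                        ssp370 = 0.45,
                                                        ssp585 = 0.60),
                               population_multipliers = c(high = 1.00,
                                                          intermediate = 0.85,
                                                          low = 0.70)) {
  horizon_start <- as.Date(horizon_start)
  horizon_end <- as.Date(horizon_end)
  scen_cfg <- cfg
  scen_cfg$date_range <- c(horizon_start, horizon_end)
  # pathways share one realisation of the weather noise and differ only in
  # trend, so cross-pathway contrasts isolate the warming signal
  temp <- do.call(rbind, lapply(seq_along(warming_per_decade_C), function(i) {
    tt <- simulate_temperature(scen_cfg, region_index = 1000L)
    days_in <- as.numeric(tt$date - horizon_start)
    trend <- warming_per_decade_C[i] / 3652.5 * pmax(0, days_in)
    data.frame(pathway = names(warming_per_decade_C)[i],
               date = tt$date, tmean_c = tt$tmean + trend)
  }))
  years <- seq(as.integer(format(horizon_start, "%Y")),
               as.integer(format(horizon_end, "%Y")))
  base_pop <- cfg$population_per_region * cfg$n_regions
  frac <- (years - years[1]) / (max(years) - years[1])
  pop <- do.call(rbind, lapply(seq_along(population_multipliers), function(i) {
    data.frame(trajectory = names(population_multipliers)[i], year = years,
               population = base_pop * population_multipliers[i]^frac,
               prop65 = prop65_at(cfg, years))
  }))
  list(temperature = temp, population = pop)
}
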