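# synthetic-data generator: temperature process, death process, scenarios

test_that("noiseless temperature stays within the seasonal envelope and is deterministic", {
  cfg <- small_cfg(n_regions = 1, temp_noise_sd = 0,
                   temp_seasonal_amplitude_C = 10, temp_mean_C = 15)
  t1 <- simulate_temperature(cfg, 1)
  expect_true(all(t1$tmean >= 5 - 1e-12 & t1$tmean <= 25 + 1e-12))
  t2 <- simulate_temperature(cfg, 1)
  expect_identical(t1, t2)
  cfg2 <- small_cfg(n_regions = 2)
  expect_false(identical(simulate_temperature(cfg2, 1)$tmean,
                         simulate_temperature(cfg2, 2)$tmean))
})

test_that("rho = 0 gives uncorrelated noise; rho > 0 gives the configured persistence", {
  cfg <- sim_config(n_regions = 1, date_range = c("1995-01-01", "2020-12-31"),
                    seed = 8, temp_ar1_rho = 0, temp_seasonal_amplitude_C = 0)
  x <- simulate_temperature(cfg, 1)$tmean - cfg$temp_mean_C
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 0.05)
  cfg2 <- sim_config(n_regions = 1, date_range = c("1995-01-01", "2020-12-31"),
                     seed = 8, temp_ar1_rho = 0.8, temp_seasonal_amplitude_C = 0)
  y <- simulate_temperature(cfg2, 1)$tmean - cfg2$temp_mean_C
  expect_equal(stats::cor(y[-1], y[-length(y)]), 0.8, tolerance = 0.05)
})

test_that("null-effect configuration draws Poisson counts at the configured rate", {
  cfg <- sim_config(n_regions = 1, date_range = c("2001-01-01", "2003-09-27"),
                    seed = 2, baseline_rate = 1e-7, population_per_region = 1e7,
                    seasonal_amplitude_logRR = 0, cold_slope_logRR_per_degC = 0,
                    dow_logRR = rep(0, 7), holiday_logRR = 0, nyd_logRR = 0,
                    nye_logRR = 0)
  p <- simulate_deaths(cfg, simulate_temperature(cfg, 1), 1)
  expect_equal(nrow(p), 1000)
  expect_lt(abs(mean(p$deaths) - 1), 3 * sqrt(1 / 1000))
})

test_that("the direct seasonal component has closed-form peak-to-trough ratio exp(2A)", {
  cfg <- small_cfg(seasonal_amplitude_logRR = log(3) / 2)
  curve <- true_seasonal_curve(cfg, component = "direct")
  # integer-grid evaluation sits within 1e-4 of the continuous closed form
  expect_equal(exp(max(curve) - min(curve)), 3, tolerance = 1e-4)
  expect_equal(which.max(curve), cfg$seasonal_peak_doy)
})

test_that("the New Year's Day multiplier is recovered empirically", {
  cfg <- sim_config(n_regions = 1, date_range = c("1995-01-01", "2020-12-31"),
                    seed = 4, baseline_rate = 2e-6,
                    seasonal_amplitude_logRR = 0, cold_slope_logRR_per_degC = 0,
                    dow_logRR = rep(0, 7), holiday_logRR = 0, nyd_logRR = log(1.7),
                    nye_logRR = 0)
  p <- simulate_deaths(cfg, simulate_temperature(cfg, 1), 1)
  plain <- !p$is_holiday & !p$is_new_years_eve & p$doy <= 31
  ratio <- mean(p$deaths[p$is_new_years_day]) / mean(p$deaths[plain])
  expect_equal(ratio, 1.7, tolerance = 0.12)
})

test_that("generator randomness flows through the seed only", {
  cfg <- small_cfg(n_regions = 2, years = 2001:2002)
  a <- simulate_panels(cfg)
  b <- simulate_panels(cfg)
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
  # and does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_panels(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("scenario temperatures carry the configured warming trend", {
  cfg <- small_cfg(n_regions = 1, temp_noise_sd = 0)
  scen <- simulate_scenarios(cfg, horizon_start = "2005-01-01",
                             horizon_end = "2054-12-31",
                             warming_per_decade_C = c(mid = 0.5),
                             population_multipliers = c(only = 1))
  tt <- scen$temperature[scen$temperature$date >= as.Date("2005-01-01"), ]
  yr <- as.integer(format(tt$date, "%Y"))
  first_year <- mean(tt$tmean_c[yr == 2005])
  final_decade <- mean(tt$tmean_c[yr >= 2045])
  expect_equal(final_decade - first_year, 2.25, tolerance = 0.2)
})

test_that("null scenarios are exchangeable with history and trajectories are monotone", {
  cfg <- small_cfg(n_regions = 1, years = 2001:2010)
  scen <- simulate_scenarios(cfg, horizon_start = "2011-01-01",
                             horizon_end = "2020-12-31",
                             warming_per_decade_C = c(null = 0),
                             population_multipliers = c(high = 1,
                                                        intermediate = 0.85,
                                                        low = 0.7))
  hist_mean <- mean(simulate_temperature(cfg, 1)$tmean)
  expect_equal(mean(scen$temperature$tmean_c), hist_mean, tolerance = 0.5)
  for (tr in c("high", "intermediate", "low")) {
    pp <- scen$population[scen$population$trajectory == tr, ]
    expect_true(all(diff(pp$population) <= 1e-9))
  }
  expect_lt(mean(scen$population$population[scen$population$trajectory == "low"]),
            mean(scen$population$population[scen$population$trajectory == "high"]))
})
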