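# pooled seasonal curve, peak/trough, PTR, AF, Monte Carlo eCIs

fake_pooled <- function(coef, vcov = diag(0, length(coef))) {
  structure(list(coef = coef, vcov = vcov, psi = diag(0, length(coef)),
                 k = 1L, method = "fixed"), class = "pooled_estimate")
}

test_that("flat and sinusoidal curves behave as the closed forms dictate", {
  flat <- seasonal_curve(fake_pooled(rep(0, 4)), df = 4)
  expect_true(all(flat$log_rr == 0))
  pt <- peak_trough(flat)
  expect_identical(unname(pt), c(1L, 1L))  # ties broken to the earliest day
  expect_equal(unname(ptr_ci(flat)["ptr"]), 1)
  # project A*cos onto the basis: max log_rr ~ 2A within 1%
  A <- 0.6
  B <- cyclic_basis(1:365, 4)
  y <- A * cos(2 * pi * (1:365 - 9) / 365)
  co <- stats::lm(y ~ B)$coefficients[-1]
  curve <- seasonal_curve(fake_pooled(unname(co)), df = 4)
  expect_equal(max(curve$log_rr), 2 * A, tolerance = 0.01)
  # wrap continuity: the year-boundary step is no bigger than the largest
  # adjacent-day step elsewhere on the grid
  expect_lte(abs(curve$log_rr[365] - curve$log_rr[1]),
             max(abs(diff(curve$log_rr))))
  # PTR equals exp(max - min) exactly
  expect_equal(unname(ptr_ci(curve)["ptr"]), exp(max(curve$log_rr)))
  expect_error(seasonal_curve(fake_pooled(rep(0, 3)), df = 4), "dimension")
})

test_that("attributable fraction matches the hand-evaluated formula", {
  curve <- seasonal_curve(fake_pooled(rep(0, 4)), df = 4)
  # flat curve -> AF = 0 whatever the weights
  w <- numeric(365); w[10] <- 50
  expect_equal(attributable_fraction(curve, NULL, weights = w), 0)
  # 100 trough days with 1 death/day + 100 days at log-RR ln 2 with 2/day
  curve$log_rr <- c(0, log(2), rep(0, 363))
  w <- numeric(365); w[1] <- 100; w[2] <- 200
  expect_equal(attributable_fraction(curve, NULL, weights = w),
               100 * (200 * 0.5) / 300, tolerance = 1e-12)
  expect_error(attributable_fraction(curve, NULL, weights = numeric(365)),
               "no deaths")
})

test_that("Monte Carlo eCIs match Wald intervals for linear statistics", {
  set.seed(2)
  V <- crossprod(matrix(rnorm(16, 0, 0.2), 4)) + diag(0.01, 4)
  pooled <- fake_pooled(c(0.3, -0.1, 0.2, 0), V)
  cc <- c(1, -1, 2, 0.5)
  stat <- function(b) sum(cc * b)
  eci <- monte_carlo_eci(pooled, stat, n_sim = 5000, seed = 9)
  est <- sum(cc * pooled$coef)
  se <- sqrt(drop(cc %*% V %*% cc))
  half_mc <- (eci$hi - eci$lo) / 2
  expect_equal(half_mc, 1.96 * se, tolerance = 0.02)
  expect_lt(abs(mean(c(eci$lo, eci$hi)) - est), 0.1 * se)
  # determinism and degeneracy
  eci2 <- monte_carlo_eci(pooled, stat, n_sim = 5000, seed = 9)
  expect_identical(eci[c("lo", "hi")], eci2[c("lo", "hi")])
  degen <- monte_carlo_eci(fake_pooled(1:2), function(b) b[1], n_sim = 100,
                           seed = 1)
  expect_equal(degen$lo, 1)
  expect_equal(degen$hi, 1)
  expect_error(monte_carlo_eci(pooled, function(b) stop("boom"), n_sim = 100,
                               seed = 1), "failed")
})

test_that("the full seasonality analysis recovers generator truth", {
  cfg <- small_cfg(n_regions = 5, years = 2001:2008, seed = 6,
                   baseline_rate = 6e-7)
  panels <- simulate_panels(cfg)
  s <- analyze_seasonality(panels, n_sim = 500, seed = 3)
  truth <- true_seasonal_curve(cfg)
  true_ptr <- exp(max(truth))
  true_af <- attributable_fraction(
    structure(list(log_rr = truth), class = "seasonal_curve"), NULL,
    weights = deaths_by_doy(panels))
  expect_equal(unname(s$ptr["ptr"]), true_ptr, tolerance = 0.12)
  expect_lt(abs(s$af["estimate"] - true_af), 4)
  expect_true(s$af["estimate"] >= 0 && s$af["estimate"] < 100)
  expect_gte(s$ptr["ptr"], 1)
  expect_true(s$trough["lo"] == round(s$trough["lo"]))
  # the winter peak is located to within a few days
  expect_lt(min(abs(c(s$peak["estimate"] - which.max(truth),
                      s$peak["estimate"] - which.max(truth) + 365))), 15)
})

test_that("period stratification is consistent and detects ordered amplitudes", {
  # one period spanning everything equals the same model run unstratified
  cfg <- small_cfg(n_regions = 3, years = 2001:2004, seed = 5)
  panels <- simulate_panels(cfg)
  one <- period_stratified_af(panels, periods = list(2001:2004),
                              method = "mm", n_sim = 200, seed = 2)[[1]]
  direct <- analyze_seasonality(panels, terms = "prop65", method = "mm",
                                n_sim = 200, seed = 2)
  expect_equal(one$af, direct$af, tolerance = 1e-10)
  expect_equal(one$ptr, direct$ptr, tolerance = 1e-10)
  # stitched generator with decreasing amplitude across periods
  amps <- c(0.9, 0.55, 0.25)
  spans <- list(2001:2003, 2004:2006, 2007:2009)
  panels2 <- lapply(1:3, function(r) {
    parts <- lapply(1:3, function(j) {
      cfgj <- sim_config(
        n_regions = 1,
        date_range = c(sprintf("%d-01-01", min(spans[[j]])),
                       sprintf("%d-12-31", max(spans[[j]]))),
        seed = 40 + 10 * r + j, baseline_rate = 2e-6,
        seasonal_amplitude_logRR = amps[j], cold_slope_logRR_per_degC = 0,
        dow_logRR = rep(0, 7), holiday_logRR = 0, nyd_logRR = 0, nye_logRR = 0)
      simulate_deaths(cfgj, simulate_temperature(cfgj, r), r)
    })
    df <- do.call(rbind, lapply(parts, as.data.frame))
    bathmort:::new_region_panel(df, tmean_history(parts[[1]]))
  })
  names(panels2) <- paste0("R", 1:3)
  strat <- period_stratified_af(panels2, periods = spans, method = "mm",
                                n_sim = 100, seed = 1)
  afs <- vapply(strat, function(s) unname(s$af["estimate"]), 0)
  expect_true(all(diff(afs) < 0))
})
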