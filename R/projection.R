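#' Aggregate region panels into a national panel
#'
#' Sums deaths and population across regions day by day; temperature and
#' prop65 are population-weighted means. The temperature history is averaged
#' the same way over the dates all regions share.
#'
#' @param panels list of [region_panel] covering identical date ranges.
#' @return a [region_panel] with region id `"national"`.
#' @export
national_panel <- function(panels) {
  base <- panels[[1]]
  for (p in panels[-1]) if (!identical(p$date, base$date))
    stop("panels must cover identical dates to aggregate nationally")
  popm <- vapply(panels, function(p) p$population, numeric(nrow(base)))
  wts <- sweep(popm, 1, rowSums(popm), "/")
  df <- as.data.frame(base)
  df$region <- "national"
  df$deaths <- as.integer(rowSums(vapply(panels, function(p) p$deaths,
                                         numeric(nrow(base)))))
  df$population <- rowSums(popm)
  df$tmean <- rowSums(vapply(panels, function(p) p$tmean,
                             numeric(nrow(base))) * wts)
  df$prop65 <- rowSums(vapply(panels, function(p) p$prop65,
                              numeric(nrow(base))) * wts)
  hists <- lapply(panels, tmean_history)
  hist <- NULL
  if (!any(vapply(hists, is.null, TRUE))) {
    dates <- Reduce(intersect, lapply(hists, function(h) as.integer(h$date)))
    if (length(dates) > 0) {
      dates <- sort(as.Date(dates, origin = "1970-01-01"))
      tm <- rowMeans(vapply(hists, function(h)
        h$tmean[match(dates, h$date)], numeric(length(dates))))
      hist <- data.frame(date = dates, tmean = tm)
    }
  }
  new_region_panel(df, hist)
}

#' Fit the projection model on historical data
#'
#' Extends the seasonality model (cyclic day-of-year spline plus temperature
#' cross-basis, population offset) with the proportion aged 65+ and a linear
#' calendar-year covariate, fitted on the historical panel. The year
#' covariate is centred at the first fitted year and can be frozen at zero
#' for a pure demographic-plus-climate projection.
#'
#' @param panels a [region_panel] (e.g. a national panel) or a list of
#'   region panels, aggregated via [national_panel()].
#' @param cb a [cb_spec()]; defaults to the panel's own distribution.
#' @param seasonal_df cyclic spline df.
#' @param freeze_year if `TRUE`, omit the calendar-year covariate (its
#'   coefficient is treated as 0 when projecting).
#' @return a `fit_result` with the specs and year centring attached.
#' @export
fit_projection_model <- function(panels, cb = NULL, seasonal_df = 4,
                                 freeze_year = FALSE) {
  panel <- if (inherits(panels, "region_panel")) panels else
    national_panel(panels)
  if (length(unique(panel$prop65)) < 2)
    stop("prop65 is constant over the fitting window; coefficient inestimable")
  if (is.null(cb)) cb <- cb_spec(panel$tmean)
  terms <- if (freeze_year) "prop65" else c("prop65", "linear_year")
  fit <- fit_region(panel, seasonal_df = seasonal_df, cb = cb, terms = terms)
  fit$year0 <- min(panel$year)
  fit$freeze_year <- freeze_year
  fit
}

#' Project daily expected deaths under crossed scenarios
#'
#' For every temperature pathway x population trajectory pair, evaluates the
#' fitted coefficients on the scenario covariates -- scenario temperature
#' through the cross-basis, scenario prop65 and calendar year, and scenario
#' population in the offset -- and aggregates expected daily deaths by
#' decade. Expected counts only (no count noise) unless `stochastic = TRUE`.
#'
#' @param fit a `fit_result` from [fit_projection_model()].
#' @param scenarios list with `temperature` (`pathway, date, tmean_c`) and
#'   `population` (`trajectory, year, population, prop65`), as from
#'   [simulate_scenarios()] or read from CSV.
#' @param baseline named character vector `c(pathway=, trajectory=)` of the
#'   baseline cell; ratios are relative to that cell's first decade.
#' @param holidays holiday calendar for scenario calendar covariates (only
#'   day-of-year enters this model, so it may be `NULL`).
#' @param stochastic draw Poisson counts around the expected dailies.
#' @param seed seed for `stochastic = TRUE`.
#' @return a `projection_table` data frame: `decade, pathway, trajectory,
#'   projected_deaths, deaths_per_population, relative_deaths,
#'   relative_per_capita`.
#' @export
project_deaths <- function(fit, scenarios,
                           baseline = c(pathway = "ssp245",
                                        trajectory = "intermediate"),
                           holidays = NULL, stochastic = FALSE, seed = 1) {
  temp <- scenarios$temperature
  pop <- scenarios$population
  pathways <- unique(temp$pathway)
  trajectories <- unique(pop$trajectory)
  rows <- list()
  for (pw in pathways) {
    tt <- temp[temp$pathway == pw, ]
    tt <- tt[order(tt$date), ]
    L <- fit$cb$max_lag
    if (any(diff(as.integer(tt$date)) != 1))
      stop("temperature pathway ", pw, " has missing days")
    eta_base <- scenario_linpred(fit, tt)
    dates <- eta_base$dates
    yr <- as.integer(format(dates, "%Y"))
    for (tr in trajectories) {
      pp <- pop[pop$trajectory == tr, ]
      if (!all(unique(yr) %in% pp$year))
        stop("population trajectory ", tr, " does not cover every horizon year")
      p65 <- pp$prop65[match(yr, pp$year)]
      popn <- pp$population[match(yr, pp$year)]
      eta <- eta_base$eta +
        fit$coef["prop65"] * p65 +
        (if (fit$freeze_year) 0 else
          fit$coef["linear_year"] * (yr - fit$year0)) +
        log(popn)
      mu <- exp(eta)
      if (stochastic) {
        set.seed(seed)
        mu <- stats::rpois(length(mu), mu)
      }
      dec <- paste0(yr %/% 10 * 10, "s")
      dsum <- tapply(mu, dec, sum)
      mpop <- tapply(popn, dec, mean)
      rows[[paste(pw, tr)]] <- data.frame(
        decade = names(dsum), pathway = pw, trajectory = tr,
        projected_deaths = as.numeric(dsum),
        deaths_per_population = as.numeric(dsum / mpop))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bl <- out[out$pathway == baseline["pathway"] &
              out$trajectory == baseline["trajectory"] &
              out$decade == min(out$decade), ]
  if (nrow(bl) != 1) stop("baseline cell not found in projections")
  out$relative_deaths <- out$projected_deaths / bl$projected_deaths
  out$relative_per_capita <- out$deaths_per_population /
    bl$deaths_per_population
  class(out) <- c("projection_table", "data.frame")
  out
}

# linear predictor pieces that do not depend on the population trajectory:
# intercept + seasonal spline + cross-basis (lag-complete days only)
scenario_linpred <- function(fit, tt) {
  L <- fit$cb$max_lag
  Z <- crossbasis(tt$tmean_c, fit$cb)
  ok <- !is.na(Z[, 1])
  dates <- tt$date[ok]
  eta <- fit$coef["(Intercept)"] +
    drop(Z[ok, , drop = FALSE] %*% fit$coef[fit$roles == "crossbasis"])
  if (!is.null(fit$seasonal_df)) {
    B <- cyclic_basis(doy365(dates), fit$seasonal_df)
    eta <- eta + drop(B %*% fit$coef[fit$roles == "seasonal"])
  }
  list(eta = eta, dates = dates)
}

#' @export
print.projection_table <- function(x, ...) {
  cat("projected deaths by decade (relative to the baseline cell):\n")
  print.data.frame(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}
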