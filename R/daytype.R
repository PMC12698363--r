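#' Fit a day-type model for one region
#'
#' Quasi-Poisson with population offset. For `target = "holiday_set"` the
#' model carries indicators for the generic holiday class, New Year's Day,
#' New Year's Eve and Coming-of-Age Day (named days take precedence over the
#' generic class, so effects do not stack); the adjusted variant adds the
#' cyclic seasonal spline, the temperature cross-basis and full
#' day-of-week x year strata. For `target = "dow"` the model carries the six
#' day-of-week contrasts versus Friday; the adjusted variant adds the
#' seasonal spline, the cross-basis, and holiday and year dummies.
#'
#' @param panel a [region_panel].
#' @param target `"holiday_set"` or `"dow"`.
#' @param adjusted logical.
#' @param cb a [cb_spec()] for the adjusted variant (use a common spec
#'   across regions, e.g. [pooled_cb_spec()]).
#' @param seasonal_df cyclic spline df for the adjusted variant.
#' @return a `fit_result`.
#' @export
daytype_model <- function(panel, target = c("holiday_set", "dow"),
                          adjusted = FALSE, cb = NULL, seasonal_df = 4) {
  target <- match.arg(target)
  if (target == "holiday_set") {
    needed <- c(holiday = any(panel$is_holiday),
                new_years_day = any(panel$is_new_years_day),
                new_years_eve = any(panel$is_new_years_eve),
                coming_of_age_day = any(panel$is_coming_of_age_day))
    if (!all(needed))
      stop("day types absent from the panel window: ",
           paste(names(needed)[!needed], collapse = ", "))
    terms <- if (adjusted) c("holiday", "dow_year_strata") else "holiday"
  } else {
    terms <- if (adjusted) c("dow", "holiday", "year") else "dow"
  }
  if (adjusted && is.null(cb))
    stop("adjusted day-type models need a cross-basis spec (cb)")
  fit_region(panel,
             seasonal_df = if (adjusted) seasonal_df else NULL,
             cb = if (adjusted) cb else NULL,
             terms = terms)
}

daytype_cols <- function(fit, target) {
  role <- if (target == "holiday_set") "holiday" else "dow"
  names(fit$roles)[fit$roles == role]
}

#' Pool day-type log relative risks across regions
#'
#' Univariate random-effects pooling (one term at a time) of the per-region
#' scalar log-RR contrasts, with Wald two-sided p-values.
#'
#' @param fits list of `fit_result` from [daytype_model()] with the same
#'   target.
#' @param target `"holiday_set"` or `"dow"`.
#' @param method pooling method (default `"reml"`).
#' @param level confidence level.
#' @return data frame `term, rr, lo, hi, p`.
#' @export
pool_daytype <- function(fits, target = "holiday_set", method = "reml",
                         level = 0.95) {
  cols <- daytype_cols(fits[[1]], target)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(cols, function(cn) {
    est <- lapply(fits, function(f)
      list(coef = f$coef[cn], vcov = f$vcov[cn, cn, drop = FALSE]))
    pl <- pool_estimates(lapply(est, `[[`, "coef"),
                         lapply(est, `[[`, "vcov"), method = method)
    b <- unname(pl$coef)
    se <- sqrt(pl$vcov[1, 1])
    data.frame(term = cn, rr = exp(b), lo = exp(b - z * se),
               hi = exp(b + z * se),
               p = 2 * stats::pnorm(-abs(b / se)))
  })
  do.call(rbind, rows)
}

#' Day-type relative risks, unadjusted and adjusted
#'
#' Runs the holiday-set and day-of-week models in each region, in both
#' unadjusted and adjusted variants, pools each term across regions, and
#' returns the combined table (one row per day-type term with unadjusted and
#' adjusted RR, CI and p-value).
#'
#' @param panels list of [region_panel].
#' @param cb [cb_spec()] for the adjusted models; defaults to
#'   [pooled_cb_spec()].
#' @param seasonal_df cyclic spline df for adjusted models.
#' @param method pooling method.
#' @return a `daytype_table` data frame: `term, model, rr, lo, hi, p`.
#' @export
analyze_daytype <- function(panels, cb = NULL, seasonal_df = 4,
                            method = "reml") {
  if (is.null(cb)) cb <- pooled_cb_spec(panels)
  out <- list()
  for (target in c("holiday_set", "dow")) {
    for (adj in c(FALSE, TRUE)) {
      fits <- lapply(panels, daytype_model, target = target, adjusted = adj,
                     cb = cb, seasonal_df = seasonal_df)
      tab <- pool_daytype(fits, target = target, method = method)
      tab$model <- if (adj) "adjusted" else "unadjusted"
      out[[paste(target, adj)]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("daytype_table", "data.frame")
  res
}

#' @export
print.daytype_table <- function(x, ...) {
  cat("day-type relative risks (pooled):\n")
  wide <- merge(x[x$model == "unadjusted", c("term", "rr", "lo", "hi", "p")],
                x[x$model == "adjusted", c("term", "rr", "lo", "hi", "p")],
                by = "term", suffixes = c("_unadj", "_adj"), sort = FALSE)
  print.data.frame(wide, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Descriptive mean daily incidence by day type
#'
#' Mean daily deaths per 10 million population by day-of-week or day-of-month
#' category, optionally excluding the December 16 - January 15 window that
#' concentrates the New Year excess.
#'
#' @param panels list of [region_panel].
#' @param by `"dow"`, `"day_of_month"` or `"holiday"`.
#' @param exclude_new_year drop Dec 16 - Jan 15 rows before aggregating.
#' @return data frame `category, incidence_per_10m`.
#' @export
daytype_incidence <- function(panels, by = c("dow", "day_of_month", "holiday"),
                              exclude_new_year = FALSE) {
  by <- match.arg(by)
  df <- do.call(rbind, lapply(panels, function(p)
    data.frame(date = p$date, deaths = p$deaths, population = p$population,
               dow = p$dow, is_holiday = p$is_holiday, doy = p$doy)))
  if (exclude_new_year) {
    md <- format(df$date, "%m-%d")
    df <- df[!(md >= "12-16" | md <= "01-15"), ]
  }
  cat_var <- switch(by,
                    dow = df$dow,
                    day_of_month = as.integer(format(df$date, "%d")),
                    holiday = ifelse(df$is_holiday, "holiday", "regular"))
  agg <- tapply(df$deaths / df$population * 1e7, cat_var, mean)
  data.frame(category = names(agg), incidence_per_10m = as.numeric(agg))
}
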