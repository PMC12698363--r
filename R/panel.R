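#' @title Region panel objects
#' @description A region panel is the aligned daily analytic series for one
#'   region: deaths, mean outdoor temperature, yearly population and
#'   proportion aged 65+ broadcast to days, and calendar covariates. It is a
#'   plain data frame of class `region_panel` with an optional
#'   `tmean_history` attribute holding the pre-window temperature series used
#'   to feed the lag structure of the cross-basis.
#' @name region_panel
NULL

new_region_panel <- function(df, history = NULL) {
  req <- c("region", "date", "deaths", "tmean", "population", "prop65",
           "year", "doy", "dow", "is_holiday", "is_new_years_day",
           "is_new_years_eve", "is_coming_of_age_day")
  stopifnot(all(req %in% names(df)))
  df <- df[order(df$date), req, drop = FALSE]
  rownames(df) <- NULL
  d <- as.integer(diff(df$date))
  if (any(d == 0)) stop("duplicate dates in panel for region ", df$region[1])
  if (any(d > 1)) {
    i <- which(d > 1)[1]
    stop(sprintf("date gap in region %s between %s and %s",
                 df$region[1], df$date[i], df$date[i + 1]))
  }
  if (any(df$deaths < 0, na.rm = TRUE)) stop("negative death counts")
  if (any(df$population <= 0)) stop("non-positive population")
  structure(df, class = c("region_panel", "data.frame"),
            tmean_history = history)
}

#' @export
print.region_panel <- function(x, ...) {
  h <- attr(x, "tmean_history")
  cat(sprintf("region_panel: region %s, %d days (%s .. %s), %d deaths%s\n",
              x$region[1], nrow(x), min(x$date), max(x$date),
              sum(x$deaths, na.rm = TRUE),
              if (is.null(h)) "" else
                sprintf(", %d days of temperature history", nrow(h))))
  print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Temperature history attached to a panel
#'
#' @param panel a `region_panel`.
#' @return data frame (`date`, `tmean`) of days preceding the panel window,
#'   or `NULL`.
#' @export
tmean_history <- function(panel) attr(panel, "tmean_history")

read_table_arg <- function(x) {
  if (is.character(x) && length(x) == 1) {
    utils::read.csv(x, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
}

#' Read daily panel tables into region panels
#'
#' Assembles one [region_panel] per region from long-format tables:
#' deaths (`region, date, deaths`), temperature (`region, date, tmean_c`;
#' empty cell = missing), yearly population (`region, year, population,
#' prop65`) and a holiday calendar (`date, label`). Temperature rows dated
#' before the first deaths date of a region become that panel's
#' `tmean_history` (they feed the lagged cross-basis only). Yearly population
#' and prop65 are broadcast to days. Missing temperatures are kept as `NA`
#' (impute with [impute_temperature()]); a missing value with no
#' same-calendar-date donor in a strictly earlier year is an error here, so
#' that a panel returned by this function is always imputable.
#'
#' Each argument may be a data frame or a path to a CSV file (header row,
#' `#` comment lines ignored).
#'
#' @param deaths,temperature,population,holidays tables or CSV paths.
#' @return named list of `region_panel`, one per region.
#' @export
read_panel <- function(deaths, temperature, population, holidays = NULL) {
  deaths <- read_table_arg(deaths)
  temperature <- read_table_arg(temperature)
  population <- read_table_arg(population)
  if (!is.null(holidays)) holidays <- read_table_arg(holidays)
  stopifnot(all(c("region", "date", "deaths") %in% names(deaths)),
            all(c("region", "date", "tmean_c") %in% names(temperature)),
            all(c("region", "year", "population", "prop65") %in%
                  names(population)))
  deaths$date <- as.Date(deaths$date)
  temperature$date <- as.Date(temperature$date)
  if (anyDuplicated(deaths[c("region", "date")]))
    stop("duplicate (region, date) rows in deaths table")
  if (anyDuplicated(temperature[c("region", "date")]))
    stop("duplicate (region, date) rows in temperature table")

  regions <- sort(unique(deaths$region))
  panels <- lapply(regions, function(r) {
    dd <- deaths[deaths$region == r, ]
    tt <- temperature[temperature$region == r, ]
    pp <- population[population$region == r, ]
    cal <- calendar_covariates(sort(dd$date), holidays)
    tmean <- tt$tmean_c[match(cal$date, tt$date)]
    check_imputable(r, cal$date, tmean, tt)
    popn <- pp$population[match(cal$year, pp$year)]
    p65 <- pp$prop65[match(cal$year, pp$year)]
    if (anyNA(popn))
      stop(sprintf("region %s: no population row for year %d",
                   r, cal$year[which(is.na(popn))[1]]))
    hist_rows <- tt[tt$date < min(cal$date), c("date", "tmean_c")]
    history <- if (nrow(hist_rows) > 0) {
      names(hist_rows) <- c("date", "tmean")
      hist_rows[order(hist_rows$date), ]
    } else NULL
    ord <- order(dd$date)
    new_region_panel(cbind(
      data.frame(region = r, deaths = as.integer(dd$deaths[ord]),
                 tmean = tmean, population = popn, prop65 = p65),
      cal[setdiff(names(cal), "date")], date = cal$date), history)
  })
  names(panels) <- regions
  panels
}

check_imputable <- function(region, dates, tmean, temp_table) {
  miss <- which(is.na(tmean))
  for (i in miss) {
    don <- donor_values(temp_table, dates[i])
    if (length(don) == 0)
      stop(sprintf(
        "region %s: temperature on %s is missing and has no same-calendar-date value in an earlier year",
        region, dates[i]))
  }
}

donor_values <- function(temp_table, date) {
  md <- format(date, "%m-%d")
  yy <- as.integer(format(date, "%Y"))
  sel <- format(temp_table$date, "%m-%d") == md &
    as.integer(format(temp_table$date, "%Y")) < yy &
    !is.na(temp_table$tmean_c)
  temp_table$tmean_c[sel]
}

#' Impute missing daily temperatures from earlier years
#'
#' Replaces each missing daily mean temperature with the arithmetic mean of
#' the non-missing values recorded on the same calendar date (month and day)
#' in strictly earlier years of the same region, taken from the panel and its
#' temperature history. Observed values are never altered, so the operation
#' is idempotent. A missing value with no earlier-year donor (e.g. in the
#' first year of the series, or February 29 with no prior leap year) is an
#' error.
#'
#' @param panel a [region_panel].
#' @return the panel with no missing `tmean`.
#' @export
impute_temperature <- function(panel) {
  miss <- which(is.na(panel$tmean))
  if (length(miss) == 0) return(panel)
  hist <- tmean_history(panel)
  all_dates <- panel$date
  all_tmean <- panel$tmean
  if (!is.null(hist)) {
    all_dates <- c(hist$date, all_dates)
    all_tmean <- c(hist$tmean, all_tmean)
  }
  md_all <- format(all_dates, "%m-%d")
  yr_all <- as.integer(format(all_dates, "%Y"))
  for (i in miss) {
    sel <- md_all == format(panel$date[i], "%m-%d") &
      yr_all < panel$year[i] & !is.na(all_tmean)
    if (!any(sel))
      stop(sprintf(
        "region %s: cannot impute %s, no same-calendar-date value in an earlier year",
        panel$region[1], panel$date[i]))
    panel$tmean[i] <- mean(all_tmean[sel])
  }
  panel
}

#' Write region panels back to the long-format CSV schemas
#'
#' Writes `deaths.csv`, `temperature.csv` (including each panel's
#' pre-window temperature history rows) and `population.csv` into `dir`.
#' The written files round-trip through [read_panel()] losslessly.
#'
#' @param panels named list of [region_panel].
#' @param dir output directory (created if needed).
#' @param header optional provenance comment lines (without the leading
#'   `"# "`), written atop each file.
#' @return `dir`, invisibly.
#' @export
write_panel_tables <- function(panels, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  deaths <- do.call(rbind, lapply(panels, function(p)
    data.frame(region = p$region, date = as.character(p$date),
               deaths = p$deaths)))
  temp <- do.call(rbind, lapply(panels, function(p) {
    h <- tmean_history(p)
    rbind(if (!is.null(h))
      data.frame(region = p$region[1], date = as.character(h$date),
                 tmean_c = h$tmean),
      data.frame(region = p$region, date = as.character(p$date),
                 tmean_c = p$tmean))
  }))
  pop <- do.call(rbind, lapply(panels, function(p) {
    u <- !duplicated(p$year)
    data.frame(region = p$region[u], year = p$year[u],
               population = p$population[u], prop65 = p$prop65[u])
  }))
  write_csv_prov(deaths, file.path(dir, "deaths.csv"), header)
  write_csv_prov(temp, file.path(dir, "temperature.csv"), header)
  write_csv_prov(pop, file.path(dir, "population.csv"), header)
  invisible(dir)
}

write_csv_prov <- function(df, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
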