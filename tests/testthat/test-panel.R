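# data model: table reading, calendar covariates, imputation, day counting

make_tables <- function(regions = c("A", "B"), start = "2001-01-01",
                        end = "2002-12-31", temp_start = NULL) {
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  tdates <- seq(as.Date(if (is.null(temp_start)) start else temp_start),
                as.Date(end), by = "day")
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  list(
    deaths = do.call(rbind, lapply(regions, function(r)
      data.frame(region = r, date = as.character(dates),
                 deaths = rep_len(c(0L, 1L, 2L), length(dates))))),
    temperature = do.call(rbind, lapply(regions, function(r)
      data.frame(region = r, date = as.character(tdates),
                 tmean_c = round(15 + 10 * cos(2 * pi * (doy365(tdates) - 219) / 365), 1)))),
    population = do.call(rbind, lapply(regions, function(r)
      data.frame(region = r, year = years, population = 1e6,
                 prop65 = 0.2 + 0.001 * (years - years[1]))))
  )
}

test_that("read_panel conserves rows, broadcasts population, and builds covariates", {
  tb <- make_tables()
  panels <- read_panel(tb$deaths, tb$temperature, tb$population,
                       holidays = make_holiday_calendar(2001:2002))
  expect_length(panels, 2)
  expect_true(all(vapply(panels, nrow, 0L) == 730))
  p <- panels$A
  expect_s3_class(p, "region_panel")
  expect_identical(p$population, rep(1e6, 730))
  # prop65 steps at the year boundary
  expect_equal(unique(p$prop65[p$year == 2002]), 0.201)
  # Monday = 1: 2001-01-01 was a Monday
  expect_identical(p$dow[p$date == as.Date("2001-01-01")], 1L)
  expect_true(p$is_new_years_day[1])
  expect_true(p$is_holiday[1])
  nye <- p$date == as.Date("2001-12-31")
  expect_true(p$is_new_years_eve[nye])
  expect_false(p$is_holiday[nye])  # Dec 31 is not a statutory holiday
  # Coming-of-Age Day moved to the second Monday of January from 2000
  expect_true(p$is_coming_of_age_day[p$date == as.Date("2001-01-08")])
  expect_false(any(p$is_coming_of_age_day[p$date == as.Date("2001-01-15")]))
})

test_that("duplicate rows, date gaps and unimputable dates are errors", {
  tb <- make_tables(regions = "A", end = "2001-12-31")
  expect_error(read_panel(rbind(tb$deaths, tb$deaths[1, ]), tb$temperature,
                          tb$population), "duplicate")
  gap <- tb$deaths[-100, ]
  expect_error(read_panel(gap, tb$temperature, tb$population), "gap")
  # missing temperature in the first year: no earlier-year donor
  tb2 <- make_tables(regions = "A", end = "2002-12-31")
  drop_date <- "2001-03-01"
  tt <- tb2$temperature[tb2$temperature$date != drop_date, ]
  tt <- rbind(tt, data.frame(region = "A", date = drop_date, tmean_c = NA))
  expect_error(read_panel(tb2$deaths, tt, tb2$population),
               "A.*2001-03-01")
})

test_that("imputation averages same-calendar-date values from earlier years only", {
  tb <- make_tables(regions = "A", start = "1996-01-01", end = "2000-12-31")
  target <- tb$temperature$date == "2000-07-15"
  donors <- c(20, 21, 22, 23)
  for (y in 1996:1999)
    tb$temperature$tmean_c[tb$temperature$date == sprintf("%d-07-15", y)] <-
      donors[y - 1995]
  tb$temperature$tmean_c[target] <- NA
  p <- read_panel(tb$deaths, tb$temperature, tb$population)$A
  p2 <- impute_temperature(p)
  expect_equal(p2$tmean[p2$date == as.Date("2000-07-15")], mean(donors))
  # observed values untouched; idempotent
  obs <- !is.na(p$tmean)
  expect_identical(p2$tmean[obs], p$tmean[obs])
  expect_identical(impute_temperature(p2), p2)
  # no missing values -> identical panel
  expect_identical(impute_temperature(p2), p2)
})

test_that("Feb 29 maps to day 59 and doy never reaches 366", {
  d <- seq(as.Date("1996-01-01"), as.Date("1996-12-31"), by = "day")
  doy <- doy365(d)
  expect_identical(max(doy), 365L)
  expect_identical(doy[d == as.Date("1996-02-29")], 59L)
  expect_identical(doy[d == as.Date("1996-02-28")], 59L)
  expect_identical(doy[d == as.Date("1996-03-01")], 60L)
  expect_identical(doy[d == as.Date("1996-12-31")], 365L)
})

test_that("count_prefecture_days matches brute-force date iteration", {
  expect_identical(count_prefecture_days("2001-01-01", "2001-12-31", 1), 365L)
  expect_identical(count_prefecture_days("1996-01-01", "1996-12-31", 2), 732L)
  set.seed(5)
  for (i in 1:10) {
    s <- as.Date("1980-01-01") + sample(0:15000, 1)
    e <- s + sample(0:18000, 1)
    k <- sample(1:50, 1)
    expect_identical(count_prefecture_days(s, e, k),
                     length(seq(s, e, by = "day")) * k)
  }
  expect_error(count_prefecture_days("2001-02-01", "2001-01-01", 1))
})

test_that("panel tables round-trip losslessly through CSV", {
  cfg <- small_cfg(n_regions = 2, years = 2001:2002)
  panels <- simulate_panels(cfg)
  dir <- withr::local_tempdir()
  write_panel_tables(panels, dir, header = "roundtrip test")
  back <- read_panel(file.path(dir, "deaths.csv"),
                     file.path(dir, "temperature.csv"),
                     file.path(dir, "population.csv"),
                     holidays = attr(panels, "holidays"))
  for (r in names(panels)) {
    a <- panels[[r]]; b <- back[[r]]
    expect_equal(as.data.frame(b)[names(a)], as.data.frame(a)[names(a)],
                 tolerance = 1e-12)
    expect_equal(tmean_history(b)$tmean, tmean_history(a)$tmean,
                 tolerance = 1e-12)
  }
})
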