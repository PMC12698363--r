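#' Common cross-basis specification from pooled temperatures
#'
#' Computes a single [cb_spec()] from the pooled temperature distribution of
#' all regions (knots at the pooled 10th/75th/90th percentiles, boundary at
#' the pooled range, reference at the pooled median), so that region
#' coefficient vectors share a basis and are poolable.
#'
#' @param panels list of [region_panel].
#' @param ... overrides passed to [cb_spec()].
#' @return a `cb_spec`.
#' @export
pooled_cb_spec <- function(panels, ...) {
  x <- unlist(lapply(panels, `[[`, "tmean"), use.names = FALSE)
  cb_spec(x, ...)
}

#' Pooled temperature-mortality association
#'
#' The two-stage temperature analysis: fit the region model (cyclic seasonal
#' spline plus temperature cross-basis), pool the cross-basis coefficient
#' block by multivariate meta-analysis, and summarise the pooled association
#' as the overall cumulative exposure-response curve, lag-specific slices,
#' and the full temperature-by-lag RR surface, all relative to the pooled
#' reference temperature.
#'
#' @param panels list of [region_panel].
#' @param cb a [cb_spec()]; defaults to [pooled_cb_spec()] on the panels.
#' @param seasonal_df cyclic spline df for the seasonal adjustment.
#' @param method pooling method.
#' @param lag_slices lag days at which to report single-lag curves.
#' @param grid temperature grid; defaults to 1-degree steps over the pooled
#'   1st-99th percentile range.
#' @param fits optional precomputed list of `fit_result` (from
#'   [fit_region()] with the same `cb`) to reuse.
#' @return a `temperature_response`: `cumulative`, `slices`, `surface`
#'   (data frames from [predict_crossbasis()]), `pooled`, `cb`, `grid`.
#' @export
analyze_temperature <- function(panels, cb = NULL, seasonal_df = 4,
                                method = "reml", lag_slices = c(0, 2, 7, 10),
                                grid = NULL, fits = NULL) {
  if (is.null(cb)) cb <- pooled_cb_spec(panels)
  x <- unlist(lapply(panels, `[[`, "tmean"), use.names = FALSE)
  if (is.null(grid)) {
    q <- stats::quantile(x, c(0.01, 0.99))
    grid <- seq(floor(q[1]), ceiling(q[2]), by = 1)
  }
  if (is.null(fits))
    fits <- lapply(panels, fit_region, seasonal_df = seasonal_df, cb = cb)
  blocks <- lapply(fits, coef_block, role = "crossbasis")
  dims <- vapply(blocks, function(b) length(b$coef), 0L)
  if (length(unique(dims)) != 1)
    stop("regions have mismatched cross-basis dimensions; use a common spec")
  pooled <- pool_estimates(lapply(blocks, `[[`, "coef"),
                           lapply(blocks, `[[`, "vcov"), method = method)
  cumulative <- predict_crossbasis(pooled$coef, pooled$vcov, cb, grid,
                                   type = "cumulative")
  slices <- lapply(lag_slices, function(l)
    predict_crossbasis(pooled$coef, pooled$vcov, cb, grid, type = "lag",
                       lag = l))
  names(slices) <- paste0("lag", lag_slices)
  surface <- predict_crossbasis(pooled$coef, pooled$vcov, cb, grid,
                                type = "surface")
  structure(list(cumulative = cumulative, slices = slices, surface = surface,
                 pooled = pooled, cb = cb, grid = grid, fits = fits),
            class = "temperature_response")
}

#' @export
print.temperature_response <- function(x, ...) {
  ref <- x$cb$ref
  at <- function(t) {
    i <- which.min(abs(x$cumulative$temp - t))
    sprintf("%.2f (%.2f-%.2f) at %g C", x$cumulative$rr[i],
            x$cumulative$lo[i], x$cumulative$hi[i], x$cumulative$temp[i])
  }
  cat(sprintf(
    "pooled cumulative temperature association (reference %.1f C):\n  RR %s; RR %s\n",
    ref, at(min(x$grid)), at(max(x$grid))))
  invisible(x)
}

#' Write temperature-response curves as CSV
#'
#' Writes `cumulative.csv` (`temp, rr, lo, hi`), one `lag<k>.csv` per slice,
#' and `surface.csv` in long format (`temp, lag, rr`).
#'
#' @param tr a `temperature_response`.
#' @param dir output directory.
#' @param header optional provenance comment line(s).
#' @return `dir`, invisibly.
#' @export
write_temperature_response <- function(tr, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_prov(tr$cumulative[c("temp", "rr", "lo", "hi")],
                 file.path(dir, "cumulative.csv"), header)
  for (nm in names(tr$slices)) {
    df <- tr$slices[[nm]]
    df$lag <- as.integer(sub("lag", "", nm))
    write_csv_prov(df[c("lag", "temp", "rr", "lo", "hi")],
                   file.path(dir, paste0(nm, ".csv")), header)
  }
  write_csv_prov(tr$surface[c("temp", "lag", "rr")],
                 file.path(dir, "surface.csv"), header)
  invisible(dir)
}
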