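#' Cyclic day-of-year spline basis
#'
#' A periodic cubic B-spline basis on the 1-365 day-of-year grid, with knots
#' evenly spaced over the cycle. The periodic B-spline design (built on
#' [mgcv::cSplineDes()]) has `df + 1` columns that form a partition of unity;
#' the first is dropped so the returned `df` columns are full rank alongside
#' a model intercept, as for ordinary B-spline bases. Basis values and first
#' two derivatives are continuous across the wrap: evaluating at `x` and
#' `x + 365` gives identical rows.
#'
#' @param doy numeric vector in `[1, 365]` (day-of-year; February 29 rows
#'   should already be mapped to 59 by [doy365()]).
#' @param df degrees of freedom (columns), at least 3; default 4.
#' @return an `n x df` matrix with attributes `df` and `knots`.
#' @export
cyclic_basis <- function(doy, df = 4) {
  if (df < 3) stop("cyclic basis needs df >= 3")
  if (any(doy < 1 | doy > 365)) stop("doy values must be in 1..365")
  knots <- seq(1, 366, length.out = df + 2)
  b <- mgcv::cSplineDes(doy, knots)[, -1, drop = FALSE]
  colnames(b) <- paste0("cyc", seq_len(df))
  structure(b, df = df, knots = knots)
}

#' Internal knots equally spaced on the log-lag scale
#'
#' @param max_lag maximum lag.
#' @param nk number of internal knots.
#' @return numeric vector of lag values.
#' @export
logknots <- function(max_lag, nk = 3) {
  exp(seq(log(1), log(max_lag), length.out = nk + 2))[seq(2, nk + 1)]
}

var_basis <- function(x, spec) {
  switch(spec$var_fun,
    ns = unclass(splines::ns(x, knots = spec$var_knots,
                             Boundary.knots = spec$var_boundary)),
    lin = matrix(x, ncol = 1),
    stop("unknown var_fun: ", spec$var_fun))
}

lag_basis <- function(spec) {
  l <- 0:spec$max_lag
  switch(spec$lag_fun,
    ns = cbind(1, unclass(splines::ns(l, knots = spec$lag_knots,
                                      Boundary.knots = range(l)))),
    const = matrix(1, length(l), 1),
    stop("unknown lag_fun: ", spec$lag_fun))
}

#' Specification of a temperature-lag cross-basis
#'
#' Defines the two marginal bases of a distributed-lag nonlinear model:
#' a temperature (exposure) basis and a lag basis, combined as a tensor
#' product. Defaults follow the dominant convention in the
#' temperature-mortality literature: natural cubic spline for temperature
#' with knots at the 10th/75th/90th percentiles of the fitting data and
#' boundary knots at its range; natural cubic spline for lag with an
#' intercept and internal knots equally spaced on the log-lag scale over
#' lags 0-21; reference at the median.
#'
#' @param x temperature series used to place data-driven defaults.
#' @param max_lag maximum lag in days (default 21).
#' @param var_fun `"ns"` (natural cubic spline) or `"lin"` (linear).
#' @param var_knots internal knots for the temperature spline.
#' @param var_boundary boundary knots for the temperature spline.
#' @param lag_fun `"ns"` or `"const"` (single constant weight).
#' @param lag_knots internal knots for the lag spline (lag units).
#' @param ref reference temperature: a constant history at `ref` maps to
#'   log-RR 0.
#' @return a `cb_spec` list.
#' @export
cb_spec <- function(x = NULL, max_lag = 21, var_fun = "ns",
                    var_knots = NULL, var_boundary = NULL,
                    lag_fun = "ns", lag_knots = NULL, ref = NULL) {
  if (max_lag < 0) stop("max_lag must be >= 0")
  if (var_fun == "ns") {
    if (is.null(var_knots))
      var_knots <- unname(stats::quantile(x, c(.10, .75, .90), na.rm = TRUE))
    if (is.null(var_boundary)) var_boundary <- range(x, na.rm = TRUE)
  }
  if (lag_fun == "ns" && is.null(lag_knots))
    lag_knots <- logknots(max_lag, 3)
  if (is.null(ref)) ref <- unname(stats::median(x, na.rm = TRUE))
  spec <- list(max_lag = as.integer(max_lag), var_fun = var_fun,
               var_knots = var_knots, var_boundary = var_boundary,
               lag_fun = lag_fun, lag_knots = lag_knots, ref = ref)
  spec$vcols <- ncol(var_basis(rep(ref, 2), spec))
  spec$lcols <- ncol(lag_basis(spec))
  class(spec) <- "cb_spec"
  spec
}

#' @export
print.cb_spec <- function(x, ...) {
  cat(sprintf(
    "cross-basis spec: lags 0..%d, %s exposure basis (%d col) x %s lag basis (%d col) = %d columns, reference %.2f\n",
    x$max_lag, x$var_fun, x$vcols, x$lag_fun, x$lcols,
    x$vcols * x$lcols, x$ref))
  invisible(x)
}

#' Build the cross-basis design matrix
#'
#' Row `t` of the cross-basis combines the exposure basis, centred at the
#' reference temperature, over lags `0..max_lag`:
#' `Z[t, (j,k)] = sum_l (v_j(x[t-l]) - v_j(ref)) * c_k(l)`.
#' A constant exposure history at the reference therefore maps to the zero
#' row (log-RR 0 at reference by construction). Lags reaching before the
#' start of `x` are served from `history` (the most recent values last);
#' rows whose lag window is still incomplete are returned as `NA` and are
#' dropped by the model fitter.
#'
#' @param x temperature series aligned to the panel rows.
#' @param spec a [cb_spec()].
#' @param history numeric vector of temperatures immediately preceding
#'   `x[1]` (oldest first), e.g. from [tmean_history()].
#' @return `length(x) x (vcols*lcols)` matrix of class `crossbasis` with the
#'   spec attached as attribute `spec`.
#' @export
crossbasis <- function(x, spec, history = numeric(0)) {
  if (anyNA(x)) stop("temperature series contains missing values; impute first")
  L <- spec$max_lag
  history <- utils::tail(history, L)
  n_hist <- length(history)
  xh <- c(history, x)
  vref <- var_basis(spec$ref, spec)
  v <- sweep(var_basis(xh, spec), 2, vref, "-")
  # pad to a full lag window so lagged row indexing never underflows; the
  # padded rows propagate NA into the lag-incomplete leading output rows
  if (n_hist < L)
    v <- rbind(matrix(NA_real_, L - n_hist, ncol(v)), v)
  C <- lag_basis(spec)
  n <- length(x)
  p <- spec$vcols * spec$lcols
  Z <- matrix(0, n, p)
  for (l in 0:L) {
    # rows of v lagged by l, aligned to output rows 1..n
    vl <- v[seq_len(n) + L - l, , drop = FALSE]
    Z <- Z + vl[, rep(seq_len(spec$vcols), each = spec$lcols), drop = FALSE] *
      matrix(C[l + 1, ], n, p, byrow = TRUE)
  }
  colnames(Z) <- paste0("cb.v", rep(seq_len(spec$vcols), each = spec$lcols),
                        ".l", rep(seq_len(spec$lcols), spec$vcols))
  structure(Z, spec = spec, class = c("crossbasis", "matrix", "array"))
}

cb_contrast_rows <- function(spec, at, lag = NULL, ref = NULL) {
  if (is.null(ref)) ref <- spec$ref
  vd <- sweep(var_basis(at, spec), 2, var_basis(ref, spec), "-")
  C <- lag_basis(spec)
  w <- if (is.null(lag)) colSums(C) else C[lag + 1, ]
  vd[, rep(seq_len(spec$vcols), each = spec$lcols), drop = FALSE] *
    matrix(w, length(at), spec$vcols * spec$lcols, byrow = TRUE)
}

#' Predict relative risks from cross-basis coefficients
#'
#' Summarises fitted (or pooled) cross-basis coefficients as relative risks
#' versus the reference temperature, with Wald confidence intervals from the
#' delta method. `type = "cumulative"` sums lag-specific effects over the
#' whole lag window (the overall cumulative exposure-response curve);
#' `type = "lag"` gives the single-lag slice at `lag`; `type = "surface"`
#' evaluates the full temperature-by-lag RR surface.
#'
#' @param coef,vcov coefficient vector and covariance matrix conforming to
#'   `spec` (`vcov` may be `NULL` for point estimates only).
#' @param spec the [cb_spec()] used to build the fitted cross-basis.
#' @param at temperature grid.
#' @param type `"cumulative"`, `"lag"` or `"surface"`.
#' @param lag lag day for `type = "lag"`.
#' @param ref optional re-centring temperature (defaults to `spec$ref`).
#' @param level confidence level (default 0.95).
#' @return data frame with columns `temp`, (`lag`,) `logrr`, `se`, `rr`,
#'   `lo`, `hi`.
#' @export
predict_crossbasis <- function(coef, vcov = NULL, spec, at,
                               type = c("cumulative", "lag", "surface"),
                               lag = NULL, ref = NULL, level = 0.95) {
  type <- match.arg(type)
  if (length(coef) != spec$vcols * spec$lcols)
    stop("coef length does not match cross-basis spec")
  if (spec$var_fun == "ns" &&
      any(at < spec$var_boundary[1] | at > spec$var_boundary[2]))
    warning("temperature grid extends beyond the spline support; extrapolating")
  if (type == "surface") {
    out <- do.call(rbind, lapply(0:spec$max_lag, function(l) {
      cbind(lag = l, predict_crossbasis(coef, vcov, spec, at, "lag",
                                        lag = l, ref = ref, level = level))
    }))
    return(out[, c("temp", "lag", "logrr", "se", "rr", "lo", "hi")])
  }
  if (type == "lag") {
    if (is.null(lag)) stop("lag must be given for type = 'lag'")
    if (lag < 0 || lag > spec$max_lag) stop("lag outside 0..max_lag")
  }
  B <- cb_contrast_rows(spec, at, lag = if (type == "lag") lag, ref = ref)
  logrr <- drop(B %*% coef)
  se <- if (is.null(vcov)) rep(0, length(at)) else
    sqrt(pmax(0, rowSums((B %*% vcov) * B)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(temp = at, logrr = logrr, se = se, rr = exp(logrr),
             lo = exp(logrr - z * se), hi = exp(logrr + z * se))
}
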