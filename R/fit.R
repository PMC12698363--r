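#' Assemble the design matrix for a region model
#'
#' Builds the quasi-Poisson design from a [region_panel] and the requested
#' terms, ordered intercept | seasonal | cross-basis | calendar. Reference
#' levels are omitted: Friday for day-of-week, the first year for year
#' dummies, and the first (Friday, first-year) cell for the day-of-week by
#' year strata. Rows whose cross-basis lag window is incomplete (no
#' temperature history) are dropped from fitting and reported in `keep`.
#'
#' @param panel a [region_panel] (temperature already imputed).
#' @param seasonal_df cyclic day-of-year spline df, or `NULL` to omit.
#' @param cb a [cb_spec()], or `NULL` to omit the cross-basis.
#' @param terms character subset of `"dow"` (6 day-of-week dummies),
#'   `"year"` (year dummies), `"holiday"` (holiday / New Year's Day /
#'   New Year's Eve / Coming-of-Age Day indicators, with the named days
#'   taking precedence over the generic holiday class), `"dow_year_strata"`
#'   (full day-of-week x year interaction dummies), `"prop65"` (linear) and
#'   `"linear_year"` (calendar year, centred at its first value).
#' @return list with `X` (design incl. intercept), `y`, `offset`
#'   (log population), `keep` (logical rows used), `roles` (column role
#'   vector) and the specs used.
#' @export
build_design <- function(panel, seasonal_df = NULL, cb = NULL,
                         terms = character()) {
  bad <- setdiff(terms, c("dow", "year", "holiday", "dow_year_strata",
                          "prop65", "linear_year"))
  if (length(bad)) stop("unknown terms: ", paste(bad, collapse = ", "))
  n <- nrow(panel)
  blocks <- list(intercept = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  keep <- rep(TRUE, n)
  if (!is.null(seasonal_df))
    blocks$seasonal <- cyclic_basis(panel$doy, seasonal_df)
  if (!is.null(cb)) {
    h <- tmean_history(panel)
    Z <- crossbasis(panel$tmean, cb,
                    history = if (is.null(h)) numeric(0) else h$tmean)
    keep <- keep & !is.na(Z[, 1])
    blocks$crossbasis <- Z
  }
  if ("holiday" %in% terms) {
    special <- panel$is_new_years_day | panel$is_coming_of_age_day
    blocks$holiday <- cbind(
      holiday = as.numeric(panel$is_holiday & !special),
      new_years_day = as.numeric(panel$is_new_years_day),
      new_years_eve = as.numeric(panel$is_new_years_eve),
      coming_of_age_day = as.numeric(panel$is_coming_of_age_day))
  }
  if ("dow" %in% terms) {
    f <- factor(panel$dow, levels = c(5, 1, 2, 3, 4, 6, 7))  # Friday ref
    M <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(M) <- paste0("dow", levels(f)[-1])
    blocks$dow <- M
  }
  if ("year" %in% terms) {
    f <- factor(panel$year)
    M <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(M) <- paste0("year", levels(f)[-1])
    blocks$year <- M
  }
  if ("dow_year_strata" %in% terms) {
    f <- interaction(factor(panel$dow, levels = c(5, 1, 2, 3, 4, 6, 7)),
                     factor(panel$year), drop = TRUE)
    M <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(M) <- paste0("stratum", levels(f)[-1])
    blocks$dow_year_strata <- M
  }
  if ("prop65" %in% terms)
    blocks$prop65 <- matrix(panel$prop65, ncol = 1,
                            dimnames = list(NULL, "prop65"))
  if ("linear_year" %in% terms)
    blocks$linear_year <- matrix(panel$year - min(panel$year), ncol = 1,
                                 dimnames = list(NULL, "linear_year"))
  X <- do.call(cbind, blocks)
  roles <- rep(names(blocks), vapply(blocks, ncol, 0L))
  names(roles) <- colnames(X)
  Xk <- X[keep, , drop = FALSE]
  qx <- qr(Xk)
  if (qx$rank < ncol(Xk)) {
    drop_cols <- colnames(Xk)[qx$pivot[(qx$rank + 1):ncol(Xk)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  list(X = X, y = panel$deaths, offset = log(panel$population), keep = keep,
       roles = roles, seasonal_df = seasonal_df, cb = cb, terms = terms,
       region = panel$region[1])
}

#' Fit a quasi-Poisson model by IRLS
#'
#' Solves the Poisson score equations with log link and offset (point
#' estimates identical to the Poisson MLE) and scales the covariance by the
#' Pearson dispersion `phi = sum(pearson residuals^2) / df_resid`. No floor
#' is applied to the dispersion by default; set `floor_dispersion = TRUE`
#' to clamp it at 1.
#'
#' @param y non-negative integer response.
#' @param X full-rank design matrix (including any intercept).
#' @param offset offset vector on the log scale.
#' @param roles optional column-role vector carried into the result.
#' @param floor_dispersion clamp dispersion at 1 (default `FALSE`).
#' @param epsilon,maxit IRLS convergence tolerance on the relative deviance
#'   change and iteration cap.
#' @return a `fit_result`: `coef`, `vcov` (dispersion-scaled), `dispersion`,
#'   `n_obs`, `df_resid`, `roles`, `fitted`.
#' @export
fit_quasipoisson <- function(y, X, offset = rep(0, length(y)), roles = NULL,
                             floor_dispersion = FALSE,
                             epsilon = 1e-8, maxit = 100) {
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (all(y == 0)) stop("all-zero response; model is not estimable")
  fit <- stats::glm.fit(X, y, offset = offset, family = stats::poisson(),
                        control = list(epsilon = epsilon, maxit = maxit))
  if (!fit$converged)
    stop(sprintf("IRLS did not converge in %d iterations (deviance %.6g)",
                 maxit, fit$deviance))
  p <- fit$rank
  if (p < ncol(X)) stop("design matrix is rank deficient")
  Rq <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rq[lower.tri(Rq)] <- 0
  piv <- fit$qr$pivot[seq_len(p)]
  cov_unscaled <- matrix(0, p, p)
  cov_unscaled[piv, piv] <- chol2inv(Rq)
  mu <- fit$fitted.values
  df_resid <- length(y) - p
  dispersion <- sum((y - mu)^2 / mu) / df_resid
  if (floor_dispersion) dispersion <- max(1, dispersion)
  vcov <- dispersion * cov_unscaled
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coef = stats::setNames(fit$coefficients, colnames(X)),
                 vcov = vcov, dispersion = dispersion,
                 n_obs = length(y), df_resid = df_resid,
                 roles = roles, fitted = mu, deviance = fit$deviance),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "quasi-Poisson fit: %d obs, %d coefficients, dispersion %.3f%s\n",
    x$n_obs, length(x$coef), x$dispersion,
    if (!is.null(x$region)) paste0(" (region ", x$region, ")") else ""))
  invisible(x)
}

#' Fit the region model from a panel
#'
#' Convenience wrapper: [build_design()] then [fit_quasipoisson()] on the
#' rows with complete lag history.
#'
#' @inheritParams build_design
#' @param ... passed to [fit_quasipoisson()].
#' @return a `fit_result` with `roles`, `region` and the basis specs
#'   attached.
#' @export
fit_region <- function(panel, seasonal_df = 4, cb = NULL,
                       terms = character(), ...) {
  d <- build_design(panel, seasonal_df = seasonal_df, cb = cb, terms = terms)
  fit <- fit_quasipoisson(d$y[d$keep], d$X[d$keep, , drop = FALSE],
                          d$offset[d$keep], roles = d$roles, ...)
  fit$region <- d$region
  fit$seasonal_df <- d$seasonal_df
  fit$cb <- d$cb
  fit
}

#' Extract a coefficient sub-vector and its covariance by column role
#'
#' @param fit a `fit_result`.
#' @param role a role name from `fit$roles` (e.g. `"seasonal"`,
#'   `"crossbasis"`, `"dow"`, `"holiday"`).
#' @return list `coef`, `vcov` restricted to that role's columns.
#' @export
coef_block <- function(fit, role) {
  idx <- which(fit$roles == role)
  if (length(idx) == 0) stop("no columns with role ", role)
  list(coef = fit$coef[idx], vcov = fit$vcov[idx, idx, drop = FALSE])
}

#' Serialize fit results to and from JSON
#'
#' Writes the pooling-relevant payload of a `fit_result` (coefficients,
#' covariance, dispersion, column roles, region id) so per-region fits can be
#' computed separately and pooled later.
#'
#' @param fit a `fit_result`.
#' @param path JSON file path.
#' @return `path` (write) or the reconstructed `fit_result` (read).
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(region = fit$region, coef = as.list(fit$coef),
                  vcov = unname(fit$vcov), dispersion = fit$dispersion,
                  n_obs = fit$n_obs, df_resid = fit$df_resid,
                  roles = as.list(fit$roles))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- names(x$coef)
  coef <- stats::setNames(unlist(x$coef), nm)
  vcov <- matrix(unlist(x$vcov), length(coef), length(coef),
                 dimnames = list(nm, nm))
  structure(list(coef = coef, vcov = vcov, dispersion = x$dispersion,
                 n_obs = x$n_obs, df_resid = x$df_resid,
                 roles = stats::setNames(unlist(x$roles), names(x$roles)),
                 region = x$region),
            class = "fit_result")
}
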