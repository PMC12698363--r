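#' Multivariate random-effects meta-analysis of region coefficients
#'
#' Pools region-specific coefficient sub-vectors (e.g. the cyclic seasonal
#' spline block, the cross-basis block, or scalar day-type contrasts) with
#' their covariance matrices. The pooled estimate is generalised least
#' squares with weights `(V_i + Psi)^-1`, where the between-region
#' covariance `Psi` is 0 for `method = "fixed"`, a moment estimator for
#' `"mm"` (the positive-semidefinite truncation of the between-region sample
#' covariance of the coefficients minus the average within-region
#' covariance), or the restricted-maximum-likelihood estimate for `"reml"`
#' (the default), maximised over the Cholesky factor of `Psi` and falling
#' back to `"mm"` if the optimiser fails. With a single region the input is
#' returned unchanged (fixed-effects identity).
#'
#' @param coefs list of numeric vectors (equal length `p`), or a `k x p`
#'   matrix, one row/element per region.
#' @param vcovs list of `p x p` covariance matrices.
#' @param method `"reml"`, `"mm"` or `"fixed"`.
#' @return a `pooled_estimate`: `coef`, `vcov`, `psi`, `k`, `method`.
#' @export
pool_estimates <- function(coefs, vcovs, method = c("reml", "mm", "fixed")) {
  method <- match.arg(method)
  if (is.matrix(coefs)) coefs <- lapply(seq_len(nrow(coefs)), function(i) coefs[i, ])
  k <- length(coefs)
  p <- length(coefs[[1]])
  stopifnot(length(vcovs) == k,
            all(vapply(coefs, length, 0L) == p),
            all(vapply(vcovs, function(v) all(dim(v) == p), TRUE)))
  B <- do.call(rbind, coefs)
  nm <- names(coefs[[1]])
  if (k == 1) {
    return(new_pooled(coefs[[1]], as_mat(vcovs[[1]], p), matrix(0, p, p),
                      1L, "fixed", nm))
  }
  if (method == "fixed")
    return(gls_pool(B, vcovs, matrix(0, p, p), "fixed", nm))
  psi_mm <- mm_psi(B, vcovs)
  if (method == "mm")
    return(gls_pool(B, vcovs, psi_mm, "mm", nm))
  if (p > k)
    warning(sprintf(
      "pooling %d-dimensional coefficients across only %d regions; Psi is weakly identified",
      p, k))
  psi <- tryCatch(reml_psi(B, vcovs, psi_mm),
                  error = function(e) {
                    warning("REML failed (", conditionMessage(e),
                            "); falling back to method-of-moments")
                    NULL
                  })
  if (is.null(psi)) gls_pool(B, vcovs, psi_mm, "mm", nm)
  else gls_pool(B, vcovs, psi, "reml", nm)
}

as_mat <- function(v, p) matrix(as.numeric(v), p, p)

new_pooled <- function(coef, vcov, psi, k, method, nm = NULL) {
  if (!is.null(nm)) {
    names(coef) <- nm
    dimnames(vcov) <- list(nm, nm)
  }
  structure(list(coef = coef, vcov = vcov, psi = psi, k = k, method = method),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "pooled estimate (%s): %d coefficients across %d regions; mean between-region SD %.4g\n",
    x$method, length(x$coef), x$k, mean(sqrt(pmax(0, diag(x$psi))))))
  invisible(x)
}

gls_pool <- function(B, vcovs, psi, method, nm = NULL) {
  p <- ncol(B)
  Ws <- lapply(vcovs, function(v) {
    tryCatch(solve(as_mat(v, p) + psi),
             error = function(e) stop("singular total covariance in pooling"))
  })
  S <- Reduce(`+`, Ws)
  Sinv <- tryCatch(solve(S),
                   error = function(e) stop("singular total covariance in pooling"))
  num <- Reduce(`+`, lapply(seq_len(nrow(B)), function(i) Ws[[i]] %*% B[i, ]))
  new_pooled(drop(Sinv %*% num), Sinv, psi, nrow(B), method, nm)
}

psd_truncate <- function(M) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
}

mm_psi <- function(B, vcovs) {
  p <- ncol(B)
  Sb <- stats::cov(B)
  Vbar <- Reduce(`+`, lapply(vcovs, as_mat, p)) / length(vcovs)
  psd_truncate(Sb - Vbar)
}

reml_loglik <- function(psi, B, vcovs) {
  p <- ncol(B)
  Ws <- lapply(vcovs, function(v) solve(as_mat(v, p) + psi))
  S <- Reduce(`+`, Ws)
  beta <- solve(S, Reduce(`+`, lapply(seq_len(nrow(B)),
                                      function(i) Ws[[i]] %*% B[i, ])))
  ll <- 0
  for (i in seq_len(nrow(B))) {
    r <- B[i, ] - drop(beta)
    ll <- ll - 0.5 * (determinant(as_mat(vcovs[[i]], p) + psi)$modulus +
                        drop(r %*% Ws[[i]] %*% r))
  }
  ll - 0.5 * determinant(S)$modulus
}

reml_psi <- function(B, vcovs, psi_start) {
  p <- ncol(B)
  # parameterise Psi = L L' with log-diagonal, free off-diagonal
  L0 <- t(chol(psi_start + diag(1e-8 * (mean(diag(psi_start)) + 1e-8), p)))
  par0 <- c(log(pmax(diag(L0), 1e-8)), L0[lower.tri(L0)])
  unpack <- function(par) {
    L <- matrix(0, p, p)
    diag(L) <- exp(par[seq_len(p)])
    L[lower.tri(L)] <- par[-seq_len(p)]
    L %*% t(L)
  }
  neg <- function(par) {
    v <- tryCatch(-reml_loglik(unpack(par), B, vcovs), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(par0, neg, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-10))
  if (!is.finite(opt$value) || opt$value >= 1e10)
    stop("restricted likelihood not finite")
  unpack(opt$par)
}
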