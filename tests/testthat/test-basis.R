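# cyclic basis and cross-basis construction / prediction

test_that("cyclic basis has df columns, wraps periodically, and spans a sinusoid", {
  b <- cyclic_basis(1:365, df = 4)
  expect_identical(ncol(b), 4L)
  # periodic continuation: day 366 reproduces day 1 through the wrap
  wrap <- mgcv::cSplineDes(c(1, 366), attr(b, "knots"))[, -1, drop = FALSE]
  expect_lt(max(abs(wrap[1, ] - wrap[2, ])), 1e-10)
  # full column rank alongside an intercept for n >= df + 1 distinct days
  sub <- cyclic_basis(c(1, 80, 160, 240, 320), df = 4)
  expect_identical(qr(cbind(1, sub))$rank, 5L)
  # least-squares projection of an annual cosine
  y <- cos(2 * pi * (1:365) / 365)
  expect_gt(summary(stats::lm(y ~ b))$r.squared, 0.99)
  expect_error(cyclic_basis(c(10, 366)), "1..365")
})

test_that("cross-basis columns reproduce the brute-force double loop", {
  set.seed(31)
  for (rep in 1:3) {
    x <- rnorm(100, 15, 8)
    hist <- rnorm(12, 15, 8)  # shorter than the lag window on purpose
    sp <- cb_spec(x, max_lag = if (rep == 1) 21 else 7)
    Z <- crossbasis(x, sp, history = hist)
    L <- sp$max_lag
    nh <- min(length(hist), L)
    xh <- c(utils::tail(hist, L), x)
    vref <- bathmort:::var_basis(sp$ref, sp)
    C <- bathmort:::lag_basis(sp)
    for (t in sample((L - nh + 1):100, 12)) {
      for (j in seq_len(sp$vcols)) for (k in seq_len(sp$lcols)) {
        s <- 0
        for (l in 0:L)
          s <- s + (bathmort:::var_basis(xh[nh + t - l], sp)[1, j] - vref[1, j]) *
            C[l + 1, k]
        expect_lt(abs(Z[t, (j - 1) * sp$lcols + k] - s), 1e-10)
      }
    }
    # rows with incomplete lag history are NA
    expect_true(all(is.na(Z[seq_len(L - nh), 1])))
    expect_false(anyNA(Z[(L - nh + 1):100, ]))
  }
})

test_that("centering, locality, and the linear moving-sum oracle hold", {
  set.seed(7)
  x <- rnorm(80, 12, 6)
  hist <- rnorm(21, 12, 6)
  sp <- cb_spec(x, max_lag = 21)
  # constant series at the reference maps to the zero matrix
  Zc <- crossbasis(rep(sp$ref, 40), sp, history = rep(sp$ref, 21))
  expect_equal(max(abs(Zc)), 0)
  # history beyond lag 21 is irrelevant
  h_long <- c(rnorm(30), hist)
  Z1 <- crossbasis(x, sp, history = h_long)
  Z2 <- crossbasis(x, sp, history = c(sample(rnorm(30)), hist))
  expect_identical(Z1, Z2)
  # linear exposure x constant lag basis = centred 22-day moving sum
  spl <- cb_spec(x, max_lag = 21, var_fun = "lin", lag_fun = "const", ref = 10)
  Zl <- crossbasis(x, spl, history = hist)
  xh <- c(hist, x)
  ms <- vapply(1:80, function(t) sum(xh[21 + t - (0:21)] - 10), 0)
  expect_lt(max(abs(drop(Zl) - ms)), 1e-10)
})

test_that("cross-basis is invariant to a common shift of data, knots and reference", {
  set.seed(12)
  x <- rnorm(60, 15, 5); hist <- rnorm(21, 15, 5)
  sp <- cb_spec(x, max_lag = 10)
  shift <- 7.3
  sp2 <- cb_spec(x + shift, max_lag = 10, var_knots = sp$var_knots + shift,
                 var_boundary = sp$var_boundary + shift, ref = sp$ref + shift)
  Z1 <- crossbasis(x, sp, history = hist)
  Z2 <- crossbasis(x + shift, sp2, history = hist + shift)
  expect_equal(unclass(Z1), unclass(Z2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # and so is the cumulative RR curve
  theta <- rnorm(sp$vcols * sp$lcols, 0, 0.05)
  g <- seq(5, 25, by = 2.5)
  p1 <- suppressWarnings(predict_crossbasis(theta, NULL, sp, g))
  p2 <- suppressWarnings(predict_crossbasis(theta, NULL, sp2, g + shift))
  expect_equal(p1$rr, p2$rr, tolerance = 1e-8)
})

test_that("prediction is centred, additive over lags, and matches the linear closed form", {
  set.seed(9)
  x <- rnorm(300, 15, 7)
  sp <- cb_spec(x, max_lag = 21)
  theta <- rnorm(sp$vcols * sp$lcols, 0, 0.03)
  V <- diag(1e-4, length(theta))
  # RR exactly 1 at the reference, CI containing 1 by construction
  at_ref <- predict_crossbasis(theta, V, sp, sp$ref)
  expect_equal(at_ref$rr, 1)
  expect_true(at_ref$lo <= 1 && at_ref$hi >= 1)
  # zero coefficients -> flat unit surface
  flat <- predict_crossbasis(rep(0, length(theta)), V, sp,
                             seq(0, 30, 5), type = "surface")
  expect_true(all(flat$rr == 1))
  # cumulative log-RR = sum of lag-slice log-RRs at every grid temperature
  g <- seq(2, 28, by = 2)
  cum <- predict_crossbasis(theta, V, sp, g)$logrr
  slc <- rowSums(vapply(0:21, function(l)
    predict_crossbasis(theta, V, sp, g, type = "lag", lag = l)$logrr,
    numeric(length(g))))
  expect_equal(cum, slc, tolerance = 1e-8)
  # constant linear effect beta per degree per lag over lags 0..21
  spl <- cb_spec(x, max_lag = 21, var_fun = "lin", lag_fun = "const")
  beta <- 0.01
  pl <- predict_crossbasis(beta, NULL, spl, g)
  expect_equal(pl$logrr, 22 * beta * (g - spl$ref), tolerance = 1e-8)
  # out-of-support grid warns but does not error
  expect_warning(predict_crossbasis(theta, V, sp, max(x) + 10), "extrapolat")
})
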