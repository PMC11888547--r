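test_that("perfect linear dependence gives cc = 1; univariate cc^2 equals R^2", {
  set.seed(1)
  X <- matrix(rnorm(600), 200, 3)
  y <- X %*% c(1, -2, 0.5)
  expect_equal(cca(X, y, reg = 0)$cc, 1, tolerance = 1e-8)

  yn <- y + rnorm(200, sd = 2)
  r <- cca(X, yn, reg = 0)
  R2 <- summary(lm(yn ~ X))$r.squared     # independent regression oracle
  expect_equal(r$cc^2, R2, tolerance = 1e-8)
})

test_that("independent sets give cc at the small-sample bias level, shrinking with n", {
  set.seed(2)
  cc_at_n <- function(n) cca(matrix(rnorm(n * 4), n, 4), rnorm(n), reg = 0)$cc
  # permutation oracle for the null scale at n = 100
  X <- matrix(rnorm(400), 100, 4); y <- rnorm(100)
  perm <- replicate(200, cca(X[sample(100), ], y, reg = 0)$cc)
  obs <- cca(X, y, reg = 0)$cc
  expect_lt(obs, quantile(perm, 0.999))
  expect_gt(obs, quantile(perm, 0.001))
  big <- mean(replicate(10, cc_at_n(2000)))
  small <- mean(replicate(10, cc_at_n(50)))
  expect_lt(big, small)
  expect_lt(big, 0.12)
})

test_that("cc is invariant to invertible transforms and symmetric in its arguments", {
  set.seed(3)
  X <- matrix(rnorm(300), 100, 3)
  Y <- matrix(rnorm(200), 100, 2)
  Y[, 1] <- Y[, 1] + 0.5 * X[, 2]
  base <- cca(X, Y, reg = 0)$cc
  for (i in 1:3) {
    A <- matrix(rnorm(9), 3, 3); B <- matrix(rnorm(4), 2, 2)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
    while (abs(det(B)) < 0.1) B <- matrix(rnorm(4), 2, 2)
    expect_equal(cca(X %*% A, Y %*% B, reg = 0)$cc, base, tolerance = 1e-8)
  }
  expect_equal(cca(Y, X, reg = 0)$cc, base, tolerance = 1e-8)
})

test_that("eigensolution attains the brute-force grid maximum on 2x2 problems", {
  set.seed(4)
  for (rep in 1:3) {
    X <- matrix(rnorm(160), 80, 2)
    Y <- matrix(rnorm(160), 80, 2)
    Y[, 2] <- Y[, 2] + 0.8 * X[, 1]
    ang <- seq(0, pi, length.out = 721)
    grid_max <- max(vapply(ang, function(a) {
      u <- c(cos(a), sin(a))
      max(vapply(ang, function(b) {
        v <- c(cos(b), sin(b))
        abs(cor(X %*% u, Y %*% v))
      }, numeric(1)))
    }, numeric(1)))
    expect_gte(cca(X, Y, reg = 0)$cc, grid_max - 1e-3)
  }
})

test_that("rank deficiency errors without regularization and is handled with it", {
  set.seed(5)
  X <- matrix(rnorm(120), 60, 2)
  X <- cbind(X, X[, 1] + X[, 2])   # exactly collinear
  y <- rnorm(60)
  expect_error(cca(X, y, reg = 0), "reg")
  expect_s3_class(cca(X, y, reg = 1e-3), "cca_result")
  expect_error(cca(X, y[-1]), "same number of samples")
})

test_that("complex CCA modes agree on real input and are phase invariant", {
  set.seed(6)
  X <- matrix(rnorm(300), 100, 3)
  y <- X[, 1] + rnorm(100)
  a <- cca_complex(X + 0i, y, mode = "complex_then_abs", reg = 0)
  b <- cca(X, y, reg = 0)
  expect_equal(a$cc, b$cc, tolerance = 1e-8)
  expect_equal(a$coef_magnitude, abs(b$u), tolerance = 1e-8)
  # multiplying a column by a unit phase leaves complex-mode cc unchanged
  Z <- matrix(complex(real = rnorm(300), imaginary = rnorm(300)), 100, 3)
  base <- cca_complex(Z, y, reg = 0)$cc
  Z2 <- Z; Z2[, 2] <- Z2[, 2] * exp(1i * 1.1)
  expect_equal(cca_complex(Z2, y, reg = 0)$cc, base, tolerance = 1e-10)
  expect_error(cca_complex(Z, y, mode = "nope"))
})

test_that("partial CCA removes the conditioner's contribution", {
  set.seed(7)
  n <- 4000
  Z <- matrix(rnorm(2 * n), n, 2)
  X <- matrix(rnorm(2 * n), n, 2)
  y <- X[, 1] + rnorm(n)
  # irrelevant conditioner: partial ~ plain
  plain <- cca(X, y, reg = 0)$cc
  part <- partial_cca(X, y, Z, reg = 0)$cc
  expect_equal(part, plain, tolerance = 0.03)
  # Y fully explained by Z
  expect_lt(partial_cca(X, Z[, 1], Z, reg = 0)$cc, 0.05)
  # constant conditioner is vacuous
  expect_equal(partial_cca(X, y, matrix(1, n, 1), reg = 0)$cc, plain,
               tolerance = 1e-8)
  # mediated dependence shrinks when conditioning on the mediator
  z <- rnorm(n); x1 <- z + rnorm(n); yy <- z + rnorm(n)
  expect_lt(partial_cca(cbind(x1), yy, cbind(z), reg = 0)$cc,
            cca(cbind(x1), yy, reg = 0)$cc - 0.2)
})

test_that("lagged CCA shifts on the slow grid with the stated sign convention", {
  set.seed(8)
  fs <- 200; K <- 5
  x <- rnorm(4000)
  y_full <- c(rep(0, 10), x[1:3990])       # y is x delayed by 10 samples (50 ms)
  ts <- ts_from_vecs(x = x, y = y_full, fs = c(x = fs, y = fs))
  tsd <- decimate(ts, "y", K)
  tf <- zscore_tfr(stft_tfr(tsd, "x", 0.1, fs / K))[[1]]
  yv <- tsd$data[[1]]$y
  at <- function(lag) lagged_cca(tf, yv, lag = lag, reg = 1e-3)$cc
  # zero lag reproduces the aligned call
  expect_equal(at(0), lagged_cca(tf, yv, reg = 1e-3)$cc)
  # delayed copy: TFR history precedes y -> maximum at negative lag
  lags <- seq(-0.2, 0.2, by = 1 / (fs / K))
  ccs <- vapply(lags, at, numeric(1))
  expect_lt(lags[which.max(ccs)], 0)
  expect_error(lagged_cca(tf, yv, lag = 30), "overlap too short")
})
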