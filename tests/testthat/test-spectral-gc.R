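test_that("decoupled systems have exactly zero spectral GC in both directions", {
  m <- small_bidir_var2()
  md <- var_model(lapply(m$coeffs, function(A) diag(diag(A))), fs = m$fs,
                  channels = m$channels)
  for (dir in list(c("x", "y"), c("y", "x"))) {
    g <- analytic_sgc(md, dir[1], dir[2])
    expect_lte(max(g$value), 1e-10)
  }
  # triangular coupling: null direction identically zero
  mu <- var_unidirectional_xy()
  expect_lte(max(analytic_sgc(mu, "y", "x")$value), 1e-10)
  myx <- var_unidirectional_yx()
  expect_lte(max(analytic_sgc(myx, "x", "y")$value), 1e-10)
  mb <- var_bidirectional41()
  expect_gt(max(analytic_sgc(mb, "y", "x")$value), 0.5)
})

test_that("unidirectional systems show the expected spectral peaks", {
  fr <- seq(0, 100, by = 0.05)
  g1 <- analytic_sgc(var_unidirectional_xy(), "x", "y", freqs = fr)
  # peaks near the transmitter's fast and slow oscillatory bands
  expect_equal(fr[which.max(g1$value)], 83.4, tolerance = 2)
  low <- fr <= 40
  expect_equal(fr[low][which.max(g1$value[low])], 11.7, tolerance = 2)
  g2 <- analytic_sgc(var_unidirectional_yx(), "y", "x", freqs = fr)
  expect_equal(fr[which.max(g2$value)], 12.8, tolerance = 2)
  # the Y->X drive is roughly twice the X->Y drive, as expected for these couplings
  expect_gt(max(g2$value) / max(g1$value), 2)
  expect_lt(max(g2$value) / max(g1$value), 3.2)
})

test_that("the Geweke identity links spectral and time-domain GC", {
  # time-domain GC from an independent long-AR regression oracle
  m <- var_unidirectional_xy()
  g <- analytic_sgc(m, "x", "y", freqs = seq(0, 100, length.out = 4096))
  ts <- simulate_var(m, 20, 30, seed = 13)
  p <- 30
  emb <- function(v, p, n) sapply(seq_len(p), function(k) v[(p + 1 - k):(n - k)])
  num <- 0; den_full <- 0; sse_r <- 0; sse_f <- 0; nn <- 0
  for (tr in ts$data) {
    n <- length(tr$y)
    Yt <- tr$y[(p + 1):n]
    Xr <- emb(tr$y, p, n)
    Xf <- cbind(Xr, emb(tr$x, p, n))
    sse_r <- sse_r + sum(lm.fit(Xr, Yt)$residuals^2)
    sse_f <- sse_f + sum(lm.fit(Xf, Yt)$residuals^2)
    nn <- nn + length(Yt)
  }
  F_time <- log(sse_r / sse_f)
  expect_equal(g$time_domain_gc, F_time, tolerance = 0.03)
})

test_that("analytic SGC is invariant to common channel scaling", {
  m <- small_bidir_var2()
  g1 <- analytic_sgc(m, "x", "y", freqs = seq(0, 100, by = 1))
  ms <- var_model(m$coeffs, fs = m$fs, noise_cov = 4 * diag(2),
                  channels = m$channels)
  g2 <- analytic_sgc(ms, "x", "y", freqs = seq(0, 100, by = 1))
  expect_equal(g1$value, g2$value, tolerance = 1e-10)
})

test_that("conditional SGC matches the bivariate value with a decoupled conditioner", {
  # moderate poles so the reduced VAR truncation error is negligible
  fs <- 200
  pc <- function(r, f) c(2 * r * cos(2 * pi * f / fs), -r^2)
  dx <- pc(0.7, 10); dy <- pc(0.75, 25); dz <- pc(0.6, 40)
  A1 <- diag(c(dx[1], dy[1], dz[1])); A2 <- diag(c(dx[2], dy[2], dz[2]))
  A1[2, 1] <- 0.4; A2[2, 1] <- -0.2
  m3 <- var_model(list(A1, A2), fs = fs, channels = c("x", "y", "z"))
  m2 <- var_model(list(A1[1:2, 1:2], A2[1:2, 1:2]), fs = fs,
                  channels = c("x", "y"))
  fr <- seq(0, 100, by = 0.5)
  gc3 <- conditional_analytic_sgc(m3, "x", "y", "z", freqs = fr,
                                  reduced_order = 200)
  gc2 <- analytic_sgc(m2, "x", "y", freqs = fr)
  expect_lt(max(abs(gc3$value - gc2$value)), 1e-6)
})

test_that("chain-system conditional SGC separates direct and mediated flow", {
  ch <- var_chain()
  fr <- seq(0, 100, by = 0.25)
  ind <- conditional_analytic_sgc(ch, "x1", "y", "x2", freqs = fr)
  expect_lt(max(ind$value), 0.02)           # no direct X1 -> Y link
  dir1 <- conditional_analytic_sgc(ch, "x2", "y", "x1", freqs = fr)
  expect_gt(max(dir1$value), 0.2)           # X2 -> Y direct
  dir2 <- conditional_analytic_sgc(ch, "x1", "x2", "y", freqs = fr)
  expect_gt(max(dir2$value), 0.2)           # X1 -> X2 direct
})

test_that("fit_var recovers parameters and selects sensible orders", {
  sp <- var_stokes_purdon()
  ts <- simulate_var(sp, 50, 10, seed = 17)
  fit <- fit_var(ts, order = 3)
  for (k in 1:3)
    expect_lt(max(abs(fit$coeffs[[k]] - sp$coeffs[[k]])), 0.05)
  expect_lt(max(abs(fit$residual_cov - diag(3))), 0.1)
  # refitting then analytic SGC reproduces the true directional structure
  gfit <- analytic_sgc(ts_fit_pair(fit, 1, 2), "x1", "x2",
                       freqs = seq(0, 60, by = 0.5))
  gtrue <- analytic_sgc(ts_fit_pair(sp, 1, 2), "x1", "x2",
                        freqs = seq(0, 60, by = 0.5))
  expect_lt(max(abs(gfit$value - gtrue$value)), 0.25 * max(gtrue$value) + 0.05)

  # white noise: coefficients near zero, IC prefers the smallest order
  wn <- white_pair(n_trials = 4, duration = 10)
  fw <- fit_var(wn, order = 1)
  expect_lt(max(abs(fw$coeffs[[1]])), 0.05)
  fsel <- fit_var(wn, order = 1:4, ic = "bic")
  expect_equal(fsel$selected_order, 1)
})

test_that("fitted VAR spectra converge to the analytic ground truth with trials", {
  m <- small_bidir_var2()
  fr <- seq(0, 100, by = 1)
  gtrue <- analytic_sgc(m, "x", "y", freqs = fr)$value
  dist <- vapply(c(5, 20, 60), function(nt) {
    fit <- fit_var(simulate_var(m, nt, 5, seed = 100 + nt), order = 2)
    sqrt(mean((analytic_sgc(fit, "x", "y", freqs = fr)$value - gtrue)^2))
  }, numeric(1))
  expect_lt(dist[3], dist[1])
  expect_lt(dist[3], 0.1)
})

test_that("MF-VAR stacks on the slow clock and tests direction by Wald blocks", {
  m <- var_unidirectional_xy()
  ts <- decimate(simulate_var(m, 20, 10, seed = 19), "y", 5)
  res <- mf_var_gc(ts, "x", "y", order = 1)
  expect_equal(res$m, 5)
  expect_equal(res$stacked_dim, 6)
  expect_lt(res$x_to_y$p_value, 1e-4)   # short-lag linear coupling is found
  expect_equal(res$x_to_y$df, 5)

  # type-I calibration on decoupled channels
  md <- var_model(lapply(m$coeffs, function(A) diag(diag(A))), fs = m$fs,
                  channels = m$channels)
  pv <- t(vapply(1:25, function(s) {
    tsn <- decimate(simulate_var(md, 4, 6, seed = 300 + s), "y", 5)
    r <- mf_var_gc(tsn, "x", "y", order = 1)
    c(r$x_to_y$p_value, r$y_to_x$p_value)
  }, numeric(2)))
  expect_lte(mean(pv[, 1] < 0.05), 0.2)
  expect_lte(mean(pv[, 2] < 0.05), 0.2)
  expect_error(mf_var_gc(ts, "y", "x"), "higher|integer")
})
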