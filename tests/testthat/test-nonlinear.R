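test_that("PAC modulation carries the phase signal in the envelope", {
  # zero phase signal -> pure tone at fa
  base <- var_model(list(matrix(0, 2, 2)), fs = 200, channels = c("x", "y"))
  base$coeffs[[1]][] <- 0
  ts <- simulate_pac(base, fa = 90, n_trials = 1, duration = 2, seed = 1)
  x0 <- attr(ts, "x0")[[1]]
  x <- ts$data[[1]]$x
  tt <- (seq_along(x) - 1) / 200
  expect_equal(x, (x0 - min(x0)) * sin(2 * pi * 90 * tt), tolerance = 1e-12)

  # narrowband phase signal: Hilbert demodulation recovers the envelope
  osc <- var_model(list(diag(c(2 * 0.95 * cos(2 * pi * 4 / 200), 0)),
                        diag(c(-0.95^2, 0))), fs = 200, channels = c("x", "y"))
  tp <- simulate_pac(osc, fa = 90, n_trials = 1, duration = 5, seed = 2)
  env_true <- attr(tp, "x0")[[1]] - min(attr(tp, "x0")[[1]])
  xa <- tp$data[[1]]$x
  # analytic-signal envelope via FFT (independent demodulation oracle)
  n <- length(xa)
  H <- fft(xa); h <- rep(0, n); h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  env_est <- Mod(fft(H * h, inverse = TRUE) / n)
  keep <- 100:(n - 100)   # edge effects
  expect_gt(cor(env_est[keep], env_true[keep]), 0.98)

  expect_error(simulate_pac(osc, fa = 150, n_trials = 1, duration = 1, seed = 1),
               "Nyquist")
})

test_that("PAC spectrum concentrates around the amplitude carrier", {
  osc <- var_model(list(diag(c(2 * 0.95 * cos(2 * pi * 4 / 200), 0)),
                        diag(c(-0.95^2, 0))), fs = 200, channels = c("x", "y"))
  tp <- simulate_pac(osc, fa = 90, n_trials = 1, duration = 10, seed = 3)
  xa <- tp$data[[1]]$x
  p <- Mod(fft(xa))^2
  fr <- (seq_along(p) - 1) * 200 / length(p)
  half <- fr <= 100
  inband <- half & fr >= 90 - 8 & fr <= 100   # fa +- 2 f0
  expect_gt(sum(p[inband]) / sum(p[half]), 0.5)
})

test_that("amplitude modulation is memoryless and saturates as specified", {
  ts <- white_pair(n_trials = 1, duration = 1)
  hi <- amplitude_modulate(ts, "x", "sigmoid", gain = 100)
  v <- hi$data[[1]]$x
  expect_true(all(v >= 0 & v <= 1))
  expect_gt(mean(v %in% range(v) | abs(v - 0.5) > 0.45), 0.9)  # sign-like
  lo <- amplitude_modulate(ts, "x", "sigmoid", gain = 1e-3)
  expect_gt(cor(lo$data[[1]]$x, ts$data[[1]]$x), 0.9999)       # linear regime
  const <- ts_from_vecs(x = rep(2, 50), fs = c(x = 10))
  cm <- amplitude_modulate(const, "x", "cosine")
  expect_equal(var(cm$data[[1]]$x), 0)
  expect_identical(hi$data[[1]]$y, ts$data[[1]]$y)             # others untouched
  expect_error(amplitude_modulate(ts, "x", "banana"))
})

test_that("logistic map presets match their parameters and stay in [0,1]", {
  un <- simulate_logistic("unidirectional", n_steps = 500, n_trials = 2, seed = 1)
  bi <- simulate_logistic("bidirectional", n_steps = 500, n_trials = 2, seed = 1)
  for (ts in list(un, bi)) {
    v <- unlist(lapply(ts$data, unlist))
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(length(ts$data[[1]]$x), 500)
  }
  # zero coupling: x trajectory independent of y coupling setting
  d0 <- simulate_logistic("custom", gamma_xy = 0, gamma_yx = 0,
                          n_steps = 200, seed = 9)
  d1 <- simulate_logistic("custom", gamma_xy = 0, gamma_yx = 0.3,
                          n_steps = 200, seed = 9)
  expect_identical(d0$data[[1]]$x, d1$data[[1]]$x)
  expect_false(identical(d0$data[[1]]$y, d1$data[[1]]$y))
  # transient removal: first kept point differs from the raw initial condition
  set.seed(2); x0 <- runif(1)
  tr <- simulate_logistic("unidirectional", n_steps = 10, transient = 100, seed = 2)
  expect_false(isTRUE(all.equal(tr$data[[1]]$x[1], x0)))
  expect_error(simulate_logistic("custom", rx = 5, seed = 1), "rx")
})

test_that("Rossler-Lorenz integration is deterministic, converges, and decouples at C = 0", {
  a <- simulate_rossler_lorenz(duration = 6, transient = 1, seed = 5)
  b <- simulate_rossler_lorenz(duration = 6, transient = 1, seed = 5)
  expect_identical(a$data, b$data)
  expect_equal(length(a$channels), 6)
  expect_equal(unname(a$fs[["y1"]]), 100)

  # C = 0: Lorenz block identical to an uncoupled run from the same state
  c0 <- simulate_rossler_lorenz(C = 0, duration = 6, transient = 1, seed = 5)
  expect_false(identical(a$data[[1]]$y2, c0$data[[1]]$y2))
  c0b <- simulate_rossler_lorenz(C = 0, duration = 6, transient = 1, seed = 5)
  expect_identical(c0$data[[1]]$y1, c0b$data[[1]]$y1)

  # step-halving convergence over the first 5 s
  s1 <- simulate_rossler_lorenz(duration = 6, transient = 0, seed = 5, substeps = 20)
  s2 <- simulate_rossler_lorenz(duration = 6, transient = 0, seed = 5, substeps = 40)
  keep <- 1:500
  for (ch in c("x1", "y1")) {
    d <- s1$data[[1]][[ch]][keep] - s2$data[[1]][[ch]][keep]
    expect_lt(rms(d) / rms(s2$data[[1]][[ch]][keep]), 1e-3)
  }
})
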