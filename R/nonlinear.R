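#' Phase-amplitude-coupled signal from a linear base system
#'
#' Simulates the 2-channel base VAR system to obtain a phase signal `X0` and
#' a target `Y`, then builds the modulated fast signal
#' `X(t) = (X0(t) + const) * sin(2 pi fa t)` with `const = -min(X0)` taken
#' per trial so the envelope is nonnegative. The causal information from X0
#' to Y is thereby carried in the spectral power of X around `fa`, i.e. the
#' X-Y coupling becomes nonlinear (phase-amplitude coupling).
#'
#' @param base_model a 2-channel [var_model] producing `(X0, Y)`.
#' @param fa amplitude-carrier frequency in Hz (default 90); must be below
#'   the base model's Nyquist frequency.
#' @param n_trials,duration,seed,burn_in as in [simulate_var()].
#' @return a [timeseries_set] with channels `x` (modulated) and `y`, plus an
#'   attribute `"x0"` holding the per-trial raw phase signals.
#' @export
simulate_pac <- function(base_model, fa = 90, n_trials, duration, seed,
                         burn_in = 500) {
  if (base_model$n_vars != 2) stop("base_model must have 2 channels")
  if (fa >= base_model$fs / 2) stop("fa is above the Nyquist frequency")
  raw <- simulate_var(base_model, n_trials, duration, seed, burn_in)
  chn <- base_model$channels
  tt <- (seq_len(round(duration * base_model$fs)) - 1) / base_model$fs
  x0 <- ts_channel(raw, chn[1])
  xmod <- lapply(x0, function(x) (x - min(x)) * sin(2 * pi * fa * tt[seq_along(x)]))
  out <- ts_replace_channel(raw, chn[1], xmod)
  out$channels <- chn
  attr(out, "x0") <- x0
  out
}

#' Memoryless amplitude modulation of one channel
#'
#' Applies a samplewise nonlinear map to one channel, leaving the others
#' untouched. `sigmoid` maps x to `1 / (1 + exp(-gain * x))`; `cosine` maps
#' x to `cos(gain * x)`. Both preserve the causal structure of the channel
#' (a memoryless map) while making its coupling to other channels nonlinear.
#'
#' @param ts a [timeseries_set].
#' @param channel channel name.
#' @param kind `"sigmoid"` or `"cosine"`.
#' @param gain slope parameter (default 2 for sigmoid, pi for cosine).
#' @export
amplitude_modulate <- function(ts, channel, kind = c("sigmoid", "cosine"),
                               gain = NULL) {
  kind <- match.arg(kind)
  if (is.null(gain)) gain <- if (kind == "sigmoid") 2 else pi
  if (!is.finite(gain)) stop("gain must be finite")
  f <- switch(kind,
              sigmoid = function(x) 1 / (1 + exp(-gain * x)),
              cosine = function(x) cos(gain * x))
  ts_replace_channel(ts, channel, lapply(ts_channel(ts, channel), f))
}

#' Two-species coupled logistic map
#'
#' Iterates
#' \deqn{X_{t+1} = X_t (r_x - r_x X_t - \gamma_{xy} Y_t)}
#' \deqn{Y_{t+1} = Y_t (r_y - r_y Y_t - \gamma_{yx} X_t)}
#' from uniform random initial conditions on [0, 1], discarding an initial
#' transient. The preset `"unidirectional"` uses `gamma_xy = 0, gamma_yx =
#' 0.32` (X drives Y); `"bidirectional"` uses `gamma_xy = 0.02, gamma_yx =
#' 0.1`.
#'
#' @param preset `"unidirectional"`, `"bidirectional"`, or `"custom"`.
#' @param rx,ry self-regulation rates (defaults 3.7 and 3.8).
#' @param gamma_xy,gamma_yx coupling constants (used when `preset =
#'   "custom"`).
#' @param n_steps samples kept per trial.
#' @param transient initial points discarded (default 100).
#' @param n_trials number of trials.
#' @param seed RNG seed.
#' @param fs nominal sampling rate attached to the map's unit time step
#'   (default 1 Hz).
#' @export
simulate_logistic <- function(preset = c("unidirectional", "bidirectional", "custom"),
                              rx = 3.7, ry = 3.8, gamma_xy = 0, gamma_yx = 0,
                              n_steps = 1000, transient = 100, n_trials = 1,
                              seed, fs = 1) {
  preset <- match.arg(preset)
  if (preset == "unidirectional") { gamma_xy <- 0; gamma_yx <- 0.32 }
  if (preset == "bidirectional") { gamma_xy <- 0.02; gamma_yx <- 0.1 }
  if (rx <= 0 || rx > 4 || ry <= 0 || ry > 4) stop("rx, ry must lie in (0, 4]")
  if (gamma_xy < 0 || gamma_yx < 0) stop("couplings must be >= 0")
  if (transient < 0) stop("transient must be >= 0")
  set.seed(seed)
  total <- n_steps + transient
  data <- lapply(seq_len(n_trials), function(i) {
    x <- numeric(total); y <- numeric(total)
    x[1] <- stats::runif(1); y[1] <- stats::runif(1)
    for (t in seq_len(total - 1)) {
      x[t + 1] <- x[t] * (rx - rx * x[t] - gamma_xy * y[t])
      y[t + 1] <- y[t] * (ry - ry * y[t] - gamma_yx * x[t])
      if (abs(x[t + 1]) > 10 || abs(y[t + 1]) > 10)
        stop("logistic map diverged at step ", t + 1)
    }
    keep <- (transient + 1):total
    list(x = x[keep], y = y[keep])
  })
  timeseries_set(data, c(x = fs, y = fs))
}

#' Coupled Rossler-Lorenz system
#'
#' Integrates the six ODEs in which a Rossler system `x1..x3` (timescale
#' `alpha`) unidirectionally drives a Lorenz system `y1..y3` through the
#' term `C * x2^2` in the dy2 equation, with a classical fixed-step
#' fourth-order Runge-Kutta integrator (step `1 / (20 fs)`), stride-sampled
#' to `fs` after dropping a transient. Initial values are drawn uniformly
#' from [-1, 1] for the Rossler block and from [5, 15] for the Lorenz block.
#'
#' @param alpha Rossler timescale constant (default 6).
#' @param C coupling strength (default 2; `C = 0` decouples the systems).
#' @param fs output sampling rate in Hz (default 100).
#' @param duration trial length in seconds (after transient).
#' @param transient seconds discarded from the start.
#' @param n_trials number of trials.
#' @param seed RNG seed.
#' @param substeps integrator steps per output sample (default 20).
#' @export
simulate_rossler_lorenz <- function(alpha = 6, C = 2, fs = 100, duration = 10,
                                    transient = 5, n_trials = 1, seed,
                                    substeps = 20) {
  if (fs <= 0 || duration <= transient || transient < 0)
    stop("need fs > 0 and duration > transient >= 0")
  set.seed(seed)
  deriv <- function(t, s, p) {
    list(c(-alpha * (s[2] + s[3]),
           alpha * (s[1] + 0.2 * s[2]),
           alpha * (0.2 + s[3] * (s[1] - 5.7)),
           10 * (-s[4] + s[5]),
           28 * s[4] - s[5] - s[4] * s[6] + C * s[2]^2,
           s[4] * s[5] - 8 / 3 * s[6]))
  }
  times <- seq(0, duration, by = 1 / (substeps * fs))
  keep_t <- seq(1, length(times), by = substeps)
  data <- lapply(seq_len(n_trials), function(i) {
    s0 <- c(stats::runif(3, -1, 1), stats::runif(3, 5, 15))
    sol <- deSolve::rk4(s0, times, deriv, parms = NULL)
    if (any(!is.finite(sol))) stop("Rossler-Lorenz integration produced non-finite state")
    samp <- sol[keep_t, -1, drop = FALSE]
    drop_n <- round(transient * fs)
    samp <- samp[(drop_n + 1):nrow(samp), , drop = FALSE]
    out <- lapply(seq_len(6), function(j) samp[, j])
    names(out) <- c("x1", "x2", "x3", "y1", "y2", "y3")
    out
  })
  fsv <- rep(fs, 6)
  names(fsv) <- c("x1", "x2", "x3", "y1", "y2", "y3")
  timeseries_set(data, fsv)
}
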