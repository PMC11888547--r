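# small models and fixtures shared across tests

# scalar AR(1) as a 1-channel var_model
ar1_model <- function(phi = 0.5, fs = 100) {
  var_model(list(matrix(phi, 1, 1)), fs = fs, channels = "x")
}

# 2-channel VAR(2) with mild bidirectional lag-1 coupling; stable
small_bidir_var2 <- function(fs = 200) {
  pc <- function(r, f) c(2 * r * cos(2 * pi * f / fs), -r^2)
  dx <- pc(0.8, 4); dy <- pc(0.85, 15)
  A1 <- diag(c(dx[1], dy[1])); A2 <- diag(c(dx[2], dy[2]))
  A1[2, 1] <- 0.15; A1[1, 2] <- 0.05
  var_model(list(A1, A2), fs = fs, channels = c("x", "y"))
}

# decoupled white-noise pair
white_pair <- function(n_trials = 4, duration = 4, fs = 200, seed = 99) {
  m <- var_model(list(matrix(0, 2, 2)), fs = fs, channels = c("x", "y"))
  simulate_var(m, n_trials, duration, seed, burn_in = 10)
}

# single-trial timeseries_set from explicit vectors
ts_from_vecs <- function(..., fs) {
  timeseries_set(list(list(...)), fs)
}

rms <- function(x) sqrt(mean(x^2))

# marginal bivariate block of a (possibly fitted) VAR model; exact when the
# dropped channels do not feed the kept ones
ts_fit_pair <- function(model, i, j) {
  var_model(lapply(model$coeffs, function(A) A[c(i, j), c(i, j)]),
            fs = model$fs, noise_cov = diag(2),
            channels = model$channels[c(i, j)])
}
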