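#' Vector autoregressive model
#'
#' Defines a stable VAR(r) process
#' \deqn{\Theta_t = \sum_{\tau=1}^r A_\tau \Theta_{t-\tau} + e_t}
#' with Gaussian innovations `e_t ~ N(0, noise_cov)`. Stability (all roots of
#' the reverse characteristic polynomial outside the unit circle, i.e.
#' companion spectral radius < 1) is enforced at construction.
#'
#' @param coeffs list of r square coefficient matrices, or an n x n x r array.
#' @param fs sampling rate in Hz.
#' @param noise_cov innovation covariance; defaults to the identity.
#' @param channels optional channel names.
#' @return an object of class `var_model`.
#' @export
var_model <- function(coeffs, fs, noise_cov = NULL, channels = NULL) {
  if (is.array(coeffs) && length(dim(coeffs)) == 3)
    coeffs <- lapply(seq_len(dim(coeffs)[3]), function(k) coeffs[, , k])
  n <- nrow(coeffs[[1]])
  for (A in coeffs)
    if (!is.matrix(A) || any(dim(A) != n)) stop("all coefficient matrices must be ", n, " x ", n)
  if (is.null(noise_cov)) noise_cov <- diag(n)
  if (any(abs(noise_cov - t(noise_cov)) > 1e-12)) stop("noise_cov must be symmetric")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("noise_cov must be positive definite")
  if (is.null(channels)) channels <- paste0("ch", seq_len(n))
  m <- structure(list(n_vars = n, order = length(coeffs), coeffs = coeffs,
                      noise_cov = noise_cov, fs = fs, channels = channels),
                 class = "var_model")
  sr <- spectral_radius(m)
  if (sr >= 1)
    stop(sprintf("unstable VAR model: companion spectral radius %.4f >= 1", sr))
  m$spectral_radius <- sr
  m
}

companion_matrix <- function(model) {
  n <- model$n_vars; r <- model$order
  C <- matrix(0, n * r, n * r)
  C[1:n, ] <- do.call(cbind, model$coeffs)
  if (r > 1) C[(n + 1):(n * r), 1:(n * (r - 1))] <- diag(n * (r - 1))
  C
}

#' Companion spectral radius of a VAR model
#' @param model a `var_model` (or a list with `coeffs`, `n_vars`, `order`).
#' @export
spectral_radius <- function(model) {
  max(Mod(eigen(companion_matrix(model), only.values = TRUE)$values))
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) model: %d channels @ %g Hz, companion spectral radius %.4f\n",
              x$order, x$n_vars, x$fs, x$spectral_radius))
  invisible(x)
}

#' Simulate multi-trial realizations of a VAR model
#'
#' Runs the VAR recursion from a zero initial state, driven by white Gaussian
#' noise, and discards an initial burn-in stretch so the returned samples are
#' effectively stationary. All trials are generated jointly (the state is a
#' channels-by-trials matrix), so a single seed reproduces the whole set.
#'
#' @param model a `var_model`.
#' @param n_trials number of independent trials.
#' @param duration trial length in seconds (after burn-in).
#' @param seed integer RNG seed.
#' @param burn_in number of initial samples to discard (default 500).
#' @return a [timeseries_set] with all channels at `model$fs`.
#' @export
simulate_var <- function(model, n_trials, duration, seed, burn_in = 500) {
  n_samp <- round(duration * model$fs)
  if (n_samp < model$order) stop("duration too short for the model order")
  if (burn_in < 0) stop("burn_in must be >= 0")
  set.seed(seed)
  n <- model$n_vars; r <- model$order
  total <- n_samp + burn_in
  L <- chol(model$noise_cov)
  # state array: n x n_trials per time step
  out <- array(0, dim = c(n, n_trials, total))
  for (t in seq_len(total)) {
    acc <- t(L) %*% matrix(rnorm(n * n_trials), n, n_trials)
    kmax <- min(r, t - 1)
    for (k in seq_len(kmax))
      acc <- acc + model$coeffs[[k]] %*% out[, , t - k, drop = FALSE][, , 1]
    out[, , t] <- acc
  }
  keep <- (burn_in + 1):total
  data <- lapply(seq_len(n_trials), function(i) {
    tr <- lapply(seq_len(n), function(j) out[j, i, keep])
    names(tr) <- model$channels
    tr
  })
  fs <- rep(model$fs, n)
  names(fs) <- model$channels
  timeseries_set(data, fs)
}

#' @rdname simulate_var
#' @param object a `var_model`.
#' @param nsim number of trials.
#' @param ... passed to [simulate_var()] (`duration`, `burn_in`).
#' @export
simulate.var_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  simulate_var(object, n_trials = nsim, seed = seed, ...)
}

#' Theoretical autocovariance sequence of a VAR model
#'
#' Solves the companion-form discrete Lyapunov equation by doubling iteration
#' and extends by the Yule-Walker recursion. Returns Gamma_k = Cov(Theta_t,
#' Theta_{t-k}) for k = 0..max_lag as an n x n x (max_lag+1) array.
#'
#' @param model a `var_model`.
#' @param max_lag largest lag.
#' @export
var_autocov <- function(model, max_lag) {
  n <- model$n_vars; r <- model$order
  C <- companion_matrix(model)
  S <- matrix(0, n * r, n * r)
  S[1:n, 1:n] <- model$noise_cov
  # doubling iteration for G = C G C' + S
  G <- S; Ak <- C
  repeat {
    G_new <- G + Ak %*% G %*% t(Ak)
    Ak <- Ak %*% Ak
    if (max(abs(G_new - G)) < 1e-14 * max(1, max(abs(G_new)))) { G <- G_new; break }
    G <- G_new
  }
  out <- array(0, dim = c(n, n, max_lag + 1))
  for (k in 0:min(max_lag, r - 1))
    out[, , k + 1] <- G[1:n, (k * n + 1):((k + 1) * n)]
  if (max_lag >= r) {
    for (k in r:max_lag) {
      acc <- matrix(0, n, n)
      for (tau in seq_len(r)) acc <- acc + model$coeffs[[tau]] %*% out[, , k - tau + 1]
      out[, , k + 1] <- acc
    }
  }
  out
}
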