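#' @name var_systems
#' @title Benchmark VAR systems with known spectral Granger causality
#'
#' @description Factory functions building the bivariate and trivariate VAR
#' benchmark systems used throughout the package, from oscillatory pole pairs
#' (modulus r, frequency f Hz) on the diagonal and fixed cross-channel
#' coefficients controlling the causal couplings. Each diagonal AR(4) block
#' is the product of two damped-oscillator AR(2) polynomials:
#' a1 = 2 r1 cos(th1) + 2 r2 cos(th2), a2 = -r1^2 - r2^2 - 4 r1 r2 cos(th1) cos(th2),
#' a3 = 2 r1 r2 (r1 cos(th1) + r2 cos(th2)), a4 = -r1^2 r2^2, with
#' th = 2 pi f / fs.
#'
#' * `var_unidirectional_xy()`: 2-channel VAR(4), X drives Y
#'   (X oscillates at 80 and 4 Hz, Y at 15 and 2 Hz; coupling -0.4, 0.7, -0.1).
#' * `var_unidirectional_yx()`: same oscillators, Y drives X
#'   (coupling 0.05, -0.05, 0.1).
#' * `var_bidirectional41()`: 2-channel VAR(41); X (4 Hz) drives Y with a
#'   3-tap coupling at lag 20 samples (0.1 s), Y (15 Hz) drives X with an
#'   11-tap band-pass coupling at lag ~30 samples (0.15 s).
#' * `var_chain()`: trivariate VAR(4) chain X1 -> X2 -> Y.
#' * `var_parallel()`: trivariate VAR(4) parallel drive X1 -> Y (weak) and
#'   X2 -> Y (strong).
#' * `var_stokes_purdon()`: trivariate VAR(3) at 120 Hz with oscillators at
#'   40, 10 and 50 Hz.
#'
#' @return a stable [var_model].
NULL

# AR(4) coefficients for the product of two pole pairs (r1,f1), (r2,f2)
pole_pair_coeffs <- function(r1, f1, r2, f2, fs) {
  c1 <- cos(2 * pi * f1 / fs); c2 <- cos(2 * pi * f2 / fs)
  c(2 * r1 * c1 + 2 * r2 * c2,
    -r1^2 - r2^2 - 4 * r1 * r2 * c1 * c2,
    2 * r1 * r2 * (r1 * c1 + r2 * c2),
    -r1^2 * r2^2)
}

# AR(2) coefficients for a single pole pair
pole_coeffs <- function(r, f, fs) c(2 * r * cos(2 * pi * f / fs), -r^2)

uni_diagonals <- function(fs = 200) {
  list(x = pole_pair_coeffs(0.9, 80, 0.8, 4, fs),
       y = pole_pair_coeffs(0.85, 15, 0.7, 2, fs))
}

#' @rdname var_systems
#' @export
var_unidirectional_xy <- function() {
  fs <- 200
  d <- uni_diagonals(fs)
  A <- lapply(1:4, function(k) diag(c(d$x[k], d$y[k])))
  A[[1]][2, 1] <- -0.4
  A[[2]][2, 1] <- 0.7
  A[[3]][2, 1] <- -0.1
  var_model(A, fs = fs, channels = c("x", "y"))
}

#' @rdname var_systems
#' @export
var_unidirectional_yx <- function() {
  fs <- 200
  d <- uni_diagonals(fs)
  A <- lapply(1:4, function(k) diag(c(d$x[k], d$y[k])))
  A[[1]][1, 2] <- 0.05
  A[[2]][1, 2] <- -0.05
  A[[3]][1, 2] <- 0.1
  var_model(A, fs = fs, channels = c("x", "y"))
}

#' @rdname var_systems
#' @export
var_bidirectional41 <- function() {
  fs <- 200
  dx <- pole_coeffs(0.8, 4, fs)    # X oscillator
  dy <- pole_coeffs(0.9, 15, fs)   # Y oscillator
  A <- lapply(1:41, function(k) matrix(0, 2, 2))
  A[[1]][1, 1] <- dx[1]; A[[1]][2, 2] <- dy[1]
  A[[2]][1, 1] <- dx[2]; A[[2]][2, 2] <- dy[2]
  xy_taps <- c(-0.175, 0.35, -0.175)            # X -> Y, lag 20 samples (0.1 s)
  for (i in 1:3) A[[20 + i]][2, 1] <- xy_taps[i]
  yx_taps <- c(0.000, 0.001, -0.014, -0.039, 0.026, 0.098,
               0.026, -0.039, -0.014, 0.001, 0.000)  # Y -> X, lag 30 samples (0.15 s)
  for (i in 1:11) A[[30 + i]][1, 2] <- yx_taps[i]
  var_model(A, fs = fs, channels = c("x", "y"))
}

tri_diagonals <- function(fs = 200) {
  # X1: 80 & 5 Hz; X2: 15 Hz; Y: 10 & 2 Hz
  list(x1 = pole_pair_coeffs(0.95, 80, 0.7, 5, fs),
       x2 = c(pole_coeffs(0.85, 15, fs), 0, 0),
       y  = pole_pair_coeffs(0.85, 10, 0.7, 2, fs))
}

#' @rdname var_systems
#' @export
var_chain <- function() {
  fs <- 200
  d <- tri_diagonals(fs)
  A <- lapply(1:4, function(k) diag(c(d$x1[k], d$x2[k], d$y[k])))
  A[[1]][2, 1] <- -0.7; A[[1]][3, 2] <- -0.3
  A[[2]][2, 1] <- 1.5;  A[[2]][3, 2] <- 0.4
  A[[3]][2, 1] <- 1;    A[[3]][3, 2] <- -0.3
  var_model(A, fs = fs, channels = c("x1", "x2", "y"))
}

#' @rdname var_systems
#' @export
var_parallel <- function() {
  fs <- 200
  d <- tri_diagonals(fs)
  A <- lapply(1:4, function(k) diag(c(d$x1[k], d$x2[k], d$y[k])))
  A[[1]][3, 1] <- -0.4; A[[1]][3, 2] <- -0.8
  A[[2]][3, 1] <- 0.7;  A[[2]][3, 2] <- 1.5
  A[[3]][3, 1] <- -0.1; A[[3]][3, 2] <- -1
  var_model(A, fs = fs, channels = c("x1", "x2", "y"))
}

#' @rdname var_systems
#' @export
var_stokes_purdon <- function() {
  fs <- 120
  d1 <- pole_coeffs(0.9, 40, fs)
  d2 <- pole_coeffs(0.7, 10, fs)
  d3 <- pole_coeffs(0.8, 50, fs)
  A1 <- diag(c(d1[1], d2[1], d3[1]))
  A1[2, 1] <- -0.356; A1[3, 2] <- -0.3098
  A2 <- diag(c(d1[2], d2[2], d3[2]))
  A2[2, 1] <- 0.7136; A2[3, 2] <- 0.5
  A3 <- matrix(0, 3, 3)
  A3[2, 1] <- -0.356; A3[3, 2] <- -0.3098
  var_model(list(A1, A2, A3), fs = fs, channels = c("x1", "x2", "x3"))
}
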