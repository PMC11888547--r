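#' Regularized canonical correlation analysis
#'
#' Solves the generalized eigenproblem for the leading canonical pair via
#' whitening: with within-set covariances ridge-regularized as
#' `S_xx + reg * mean(diag(S_xx)) * I`, the canonical correlation is the
#' leading singular value of `S_xx^{-1/2} S_xy S_yy^{-1/2}`. Works for real
#' and complex `X` (Hermitian covariances); `Y` is real. With univariate `Y`
#' and `reg = 0`, `cc^2` equals the coefficient of determination of
#' regressing `Y` on `X`.
#'
#' @param X samples x p matrix (real or complex).
#' @param Y samples x q real matrix (or vector).
#' @param reg relative ridge regularization (default `1e-3`); scaled by the
#'   mean diagonal of each within-set covariance. `0` disables it.
#' @return an object of class `cca_result` with elements `cc` (in [0, 1]),
#'   `u`, `v` (leading weight vectors), `coef_magnitude` (`Mod(u)`),
#'   `loading` (structure correlations: `|corr|` of each X column with the
#'   canonical variate of Y), `n_samples` and `regularization`.
#' @export
cca <- function(X, Y, reg = 1e-3) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of samples")
  if (reg < 0) stop("reg must be >= 0")
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  Sxx <- crossprod(Conj(Xc), Xc) / (n - 1)
  Syy <- crossprod(Yc, Yc) / (n - 1)
  Sxy <- crossprod(Conj(Xc), Yc) / (n - 1)
  res <- cca_from_cov(Sxx, Syy, Sxy, reg)
  res$n_samples <- n
  res$loading <- structure_loadings(Xc, Yc, res$v)
  res
}

# structure correlations: |corr| of each X column with the canonical variate
# of the Y set (for univariate Y this is |corr(X_j, y)|); stable under
# collinear X columns, unlike the weight vector
structure_loadings <- function(Xc, Yc, v) {
  ty <- as.matrix(Yc) %*% v
  ty <- ty - mean(ty)
  num <- Mod(drop(crossprod(Conj(Xc), ty)))
  den <- sqrt(colSums(Mod(Xc)^2) * sum(Mod(ty)^2))
  den[den < .Machine$double.eps] <- 1
  as.numeric(num / den)
}

# leading canonical pair from covariance blocks (real or complex Hermitian)
cca_from_cov <- function(Sxx, Syy, Sxy, reg) {
  Sxx_r <- ridge(Sxx, reg)
  Syy_r <- ridge(Syy, reg)
  Wx <- inv_sqrt_hermitian(Sxx_r, reg == 0)
  Wy <- inv_sqrt_hermitian(Syy_r, reg == 0)
  Tm <- Wx %*% Sxy %*% Wy
  sv <- svd(Tm, nu = 1, nv = 1)
  cc <- min(1, sv$d[1])
  u <- drop(Wx %*% sv$u[, 1])
  v <- drop(Wy %*% sv$v[, 1])
  # fix phase/sign: largest-modulus entry of u real-positive
  piv <- which.max(Mod(u))
  ph <- u[piv] / Mod(u[piv])
  u <- u / ph
  if (is.complex(v)) v <- v / ph
  structure(list(cc = cc, u = u, v = v, coef_magnitude = Mod(u),
                 regularization = reg),
            class = "cca_result")
}

ridge <- function(S, reg) {
  if (reg == 0) return(S)
  S + diag(reg * mean(Re(diag(S))), nrow(S))
}

inv_sqrt_hermitian <- function(S, strict) {
  e <- eigen((S + Conj(t(S))) / 2, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (any(e$values < tol)) {
    if (strict)
      stop("rank-deficient within-set covariance; use reg > 0 for a regularized solution")
    e$values <- pmax(e$values, tol)
  }
  e$vectors %*% (Conj(t(e$vectors)) / sqrt(e$values))
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("Canonical correlation: %.4f (p = %d, q = %d, n = %s, reg = %g)\n",
              x$cc, length(x$u), length(x$v),
              if (is.null(x$n_samples)) "?" else x$n_samples, x$regularization))
  invisible(x)
}

#' CCA between a complex TFR matrix and a real series
#'
#' Two variants of the same estimator. `complex_then_abs` solves the CCA
#' with Hermitian covariances on the complex matrix and reports the modulus
#' of the complex weights; `abs_then_cca` replaces `X` by its elementwise
#' modulus first and runs real CCA. The magnitude route is sensitive to
#' causal information carried in spectral power (phase-amplitude coupling),
#' which the complex route averages out.
#'
#' @param X samples x p complex matrix.
#' @param Y samples x q real matrix.
#' @param mode `"complex_then_abs"` or `"abs_then_cca"`.
#' @param reg ridge regularization, as in [cca()].
#' @export
cca_complex <- function(X, Y, mode = c("complex_then_abs", "abs_then_cca"),
                        reg = 1e-3) {
  mode <- match.arg(mode)
  if (mode == "abs_then_cca") X <- Mod(X)
  cca(X, Y, reg = reg)
}

#' Partial canonical correlation analysis
#'
#' Maximal correlation between projections of `X` and `Y` after removing the
#' linear influence of `Z` from all covariance blocks:
#' `S_uv|z = S_uv - S_uz S_zz^{-1} S_zv`. All variables are standardized
#' (columns centered; real columns also scaled to unit variance) before the
#' partialization, and the same whitened eigenproblem as [cca()] is solved on
#' the partialized blocks.
#'
#' @param X samples x p matrix (real or complex).
#' @param Y samples x q real matrix.
#' @param Z samples x k conditioning matrix (real or complex). Constant
#'   columns are dropped (a constant conditioner is vacuous).
#' @param reg ridge regularization, as in [cca()].
#' @export
partial_cca <- function(X, Y, Z, reg = 1e-3) {
  X <- as.matrix(X); Y <- as.matrix(Y); Z <- as.matrix(Z)
  if (nrow(X) != nrow(Y) || nrow(X) != nrow(Z))
    stop("X, Y, Z must have the same number of samples")
  n <- nrow(X)
  std <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    s <- sqrt(colMeans(Mod(M)^2) * n / max(1, n - 1))
    keep <- s > .Machine$double.eps * 10
    sweep(M[, keep, drop = FALSE], 2, s[keep], "/")
  }
  Xc <- std(X); Yc <- std(Y); Zc <- std(Z)
  if (ncol(Zc) == 0) return(cca(Xc, Yc, reg = reg))
  cp <- function(A, B) crossprod(Conj(A), B) / (n - 1)
  Szz <- ridge(cp(Zc, Zc), reg)
  if (reg == 0 && rcond(Re(Szz)) < 1e-12)
    stop("singular conditioning covariance; use reg > 0")
  SzzI <- solve(Szz)
  part <- function(Suv, Suz, Szv) Suv - Suz %*% SzzI %*% Szv
  Sxx <- part(cp(Xc, Xc), cp(Xc, Zc), cp(Zc, Xc))
  Syy <- part(cp(Yc, Yc), cp(Yc, Zc), cp(Zc, Yc))
  Sxy <- part(cp(Xc, Yc), cp(Xc, Zc), cp(Zc, Yc))
  # a set fully explained by the conditioner has no residual variance left:
  # the partial canonical correlation is zero by convention
  if (mean(Re(diag(as.matrix(Syy)))) < 1e-10 ||
      mean(Re(diag(as.matrix(Sxx)))) < 1e-10) {
    return(structure(list(cc = 0, u = rep(0, ncol(Xc)), v = rep(0, ncol(Yc)),
                          coef_magnitude = rep(0, ncol(Xc)),
                          loading = rep(0, ncol(Xc)),
                          regularization = reg, n_samples = n),
                     class = "cca_result"))
  }
  res <- cca_from_cov(Sxx, Syy, Sxy, reg)
  res$n_samples <- n
  res$loading <- structure_loadings(Xc, Yc, res$v)
  res
}

#' Lagged CCA between a TFR and a slow series
#'
#' Shifts the slow series by a signed lag on its own sample grid, truncates
#' both sides to the overlap and runs [cca_complex()] (or [partial_cca()]
#' when a conditioner is supplied). A negative lag pairs the TFR with later
#' samples of the slow series, i.e. the TFR history precedes the slow
#' series: large canonical correlation at negative lag is evidence for
#' information flow from the fast channel to the slow one.
#'
#' @param tfr a `tfr` object (one trial; typically z-scored).
#' @param y slow-series vector for the same trial.
#' @param lag signed lag in seconds; rounded to the slow sample grid.
#' @param mode CCA variant, see [cca_complex()].
#' @param reg ridge regularization.
#' @param z optional conditioning matrix aligned to the slow clock (same
#'   trial), with rows indexed like `y`.
#' @param min_overlap minimum aligned samples (default 50).
#' @export
lagged_cca <- function(tfr, y, lag = 0, mode = "complex_then_abs", reg = 1e-3,
                       z = NULL, min_overlap = 50) {
  d <- as.integer(round(lag * tfr$target_fs))
  al <- align_tfr_y(tfr, y, d, z)
  if (nrow(al$X) < min_overlap)
    stop("overlap too short at lag ", lag, " s: ", nrow(al$X), " samples")
  ys <- as.numeric(scale(al$y))
  if (is.null(al$z)) cca_complex(al$X, ys, mode = mode, reg = reg)
  else {
    X <- if (mode == "abs_then_cca") Mod(al$X) else al$X
    partial_cca(X, ys, al$z, reg = reg)
  }
}

# pair TFR bin i with slow sample (i - 1 + y_offset) - d, truncated to overlap
align_tfr_y <- function(tfr, y, d, z = NULL) {
  nb <- nrow(tfr$values)
  yi <- seq_len(nb) - 1 + tfr$y_offset - d
  keep <- which(yi >= 1 & yi <= length(y))
  zs <- NULL
  if (!is.null(z)) {
    zs <- as.matrix(z)[yi[keep], , drop = FALSE]
    good <- !apply(is.na(zs), 1, any)   # conditioner undefined outside TFR span
    zs <- zs[good, , drop = FALSE]
    keep <- keep[good]
  }
  list(X = tfr$values[keep, , drop = FALSE], y = y[yi[keep]], z = zs)
}
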