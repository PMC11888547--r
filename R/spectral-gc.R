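#' Analytic spectral Granger causality from VAR coefficients
#'
#' Computes the Geweke frequency-domain Granger causality of a bivariate (or
#' pairwise-marginal bivariate block of a) VAR model with known
#' coefficients. The spectral transfer matrix is
#' `H(f) = (I - sum_tau A_tau exp(-2 pi i f tau / fs))^{-1}`; for correlated
#' innovations the standard left-multiplication normalization
#' `H~_yx = H_yx + (S_yx / S_xx) H_yy` is applied, and
#' \deqn{f_{x \to y}(f) = \log \frac{S_{yy}(f)}{S_{yy}(f) - |\tilde H_{yx}(f)|^2 \Sigma_{xx}}}
#' The frequency-integrated time-domain value `(2/fs) * integral` is
#' attached (Geweke identity).
#'
#' @param model a [var_model] with exactly 2 channels (for conditional
#'   trivariate causality see [conditional_analytic_sgc()]).
#' @param from,to source and target channel (name or index).
#' @param freqs frequency grid in Hz; default 512 points on [0, fs/2].
#' @return an object of class `sgc_spectrum`: `freqs`, `value` (nonnegative
#'   per-frequency GC), `direction`, `time_domain_gc`.
#' @export
analytic_sgc <- function(model, from, to, freqs = NULL) {
  if (model$n_vars != 2)
    stop("analytic_sgc is bivariate; use conditional_analytic_sgc for 3 channels")
  i_from <- channel_index(model, from)
  i_to <- channel_index(model, to)
  if (i_from == i_to) stop("'from' and 'to' must differ")
  if (is.null(freqs)) freqs <- seq(0, model$fs / 2, length.out = 512)
  S <- model$noise_cov
  val <- vapply(freqs, function(f) {
    H <- transfer_matrix(model, f)
    Sp <- H %*% S %*% Conj(t(H))
    Syy <- Re(Sp[i_to, i_to])
    Ht <- H[i_to, i_from] + (S[i_to, i_from] / S[i_from, i_from]) * H[i_to, i_to]
    Sxx_cond <- S[i_from, i_from] - S[i_from, i_to]^2 / S[i_to, i_to]
    den <- Syy - Mod(Ht)^2 * Sxx_cond
    if (den <= 0) den <- .Machine$double.xmin
    max(0, log(Syy / den))
  }, numeric(1))
  new_sgc(freqs, val, model, from = i_from, to = i_to)
}

transfer_matrix <- function(model, f) {
  n <- model$n_vars
  z <- exp(-2i * pi * f * seq_len(model$order) / model$fs)
  Aw <- diag(n) + 0i
  for (k in seq_len(model$order)) Aw <- Aw - model$coeffs[[k]] * z[k]
  H <- tryCatch(solve(Aw), error = function(e)
    stop(sprintf("singular transfer matrix at %g Hz", f)))
  H
}

new_sgc <- function(freqs, val, model, from, to) {
  structure(list(freqs = freqs, value = val,
                 direction = paste(model$channels[from], "->", model$channels[to]),
                 time_domain_gc = trapz(freqs, val) * 2 / model$fs),
            class = "sgc_spectrum")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.sgc_spectrum <- function(x, ...) {
  i <- which.max(x$value)
  cat(sprintf("Spectral GC %s: peak %.4f at %.2f Hz; time-domain GC %.4f\n",
              x$direction, x$value[i], x$freqs[i], x$time_domain_gc))
  invisible(x)
}

#' @export
plot.sgc_spectrum <- function(x, ...) {
  graphics::plot(x$freqs, x$value, type = "l", xlab = "frequency (Hz)",
                 ylab = "spectral GC", main = x$direction, ...)
}

channel_index <- function(model, ch) {
  if (is.character(ch)) {
    i <- match(ch, model$channels)
    if (is.na(i)) stop("unknown channel: ", ch)
    i
  } else as.integer(ch)
}

#' Conditional spectral Granger causality from VAR coefficients
#'
#' Geweke's conditional frequency-domain causality `from -> to | cond` for a
#' trivariate model, via the reduced-model construction: the exact
#' autocovariance sequence of the (target, conditioning) subprocess is
#' computed from the full model, a truncated VAR is fitted to it by
#' block-Toeplitz Yule-Walker equations, and the causality is measured from
#' the source innovations into the reduced model's target innovation
#' process.
#'
#' @param model a [var_model] with 3 channels.
#' @param from,to,cond source, target and conditioning channels.
#' @param freqs frequency grid in Hz; default 512 points on [0, fs/2].
#' @param reduced_order truncation order of the reduced VAR (default 200);
#'   the reduced subprocess is generically VAR(infinity) with coefficients
#'   decaying at the pole moduli, so the truncation error is geometric.
#' @export
conditional_analytic_sgc <- function(model, from, to, cond, freqs = NULL,
                                     reduced_order = 200) {
  if (model$n_vars != 3) stop("conditional_analytic_sgc expects 3 channels")
  i_f <- channel_index(model, from)
  i_t <- channel_index(model, to)
  i_c <- channel_index(model, cond)
  if (anyDuplicated(c(i_f, i_t, i_c))) stop("channels must be distinct")
  if (is.null(freqs)) freqs <- seq(0, model$fs / 2, length.out = 512)
  S <- model$noise_cov
  if (max(abs(S - diag(diag(S)))) > 1e-12)
    stop("conditional SGC currently assumes diagonal innovation covariance")
  # reduced model on (to, cond)
  G <- var_autocov(model, reduced_order)
  sub <- c(i_t, i_c)
  Gs <- G[sub, sub, , drop = FALSE]
  red <- yule_walker_var(Gs, reduced_order)
  val <- vapply(freqs, function(f) {
    H <- transfer_matrix(model, f)          # n x n, full innovations
    z <- exp(-2i * pi * f * seq_len(reduced_order) / model$fs)
    BB <- diag(2) + 0i                      # reduced inverse transfer
    for (k in seq_len(reduced_order)) BB <- BB - red$A[, , k] * z[k]
    # rows: (to, cond) reduced innovations expressed in full innovations
    Q <- BB %*% H[sub, , drop = FALSE]
    num <- Re((Q %*% S %*% Conj(t(Q)))[1, 1])
    den <- num - Mod(Q[1, i_f])^2 * S[i_f, i_f]
    if (den <= 0) den <- .Machine$double.xmin
    max(0, log(num / den))
  }, numeric(1))
  structure(list(freqs = freqs, value = val,
                 direction = sprintf("%s -> %s | %s", model$channels[i_f],
                                     model$channels[i_t], model$channels[i_c]),
                 time_domain_gc = trapz(freqs, val) * 2 / model$fs),
            class = "sgc_spectrum")
}

# solve the block-Toeplitz Yule-Walker system Gamma_j = sum_k A_k Gamma_{j-k}
# for A_1..A_q given Gamma_0..Gamma_q (n x n x (q+1)); returns coefficient
# array and innovation covariance
yule_walker_var <- function(Garr, q) {
  n <- dim(Garr)[1]
  blk <- function(k) if (k >= 0) Garr[, , k + 1] else t(Garr[, , -k + 1])
  Tm <- matrix(0, n * q, n * q)
  for (i in seq_len(q)) for (j in seq_len(q))
    Tm[((i - 1) * n + 1):(i * n), ((j - 1) * n + 1):(j * n)] <- blk(j - i)
  R <- do.call(cbind, lapply(seq_len(q), function(j) blk(j)))  # [G1 ... Gq]
  A_flat <- R %*% solve(Tm)
  A <- array(0, dim = c(n, n, q))
  Sig <- Garr[, , 1]
  for (k in seq_len(q)) {
    A[, , k] <- A_flat[, ((k - 1) * n + 1):(k * n)]
    Sig <- Sig - A[, , k] %*% t(Garr[, , k + 1])
  }
  list(A = A, Sigma = (Sig + t(Sig)) / 2)
}

#' Fit a VAR model by multi-trial least squares
#'
#' Pools lagged regressors across trials (no cross-trial lag leakage) and
#' estimates coefficient matrices equation-by-equation by ordinary least
#' squares; the residual covariance is returned in the fitted model. An
#' optional information-criterion scan selects the order.
#'
#' @param ts a [timeseries_set] with all channels at a common rate.
#' @param order model order r, or a vector of candidate orders to scan.
#' @param ic criterion for the scan, `"aic"` or `"bic"`.
#' @param demean subtract per-trial channel means first (default TRUE).
#' @return a [var_model] with extra fields `residual_cov`, `selected_order`,
#'   `ic_table`.
#' @export
fit_var <- function(ts, order, ic = c("aic", "bic"), demean = TRUE) {
  ic <- match.arg(ic)
  fs <- unique(unname(ts$fs))
  if (length(fs) != 1) stop("fit_var requires a common sampling rate")
  trials <- lapply(ts$data, function(tr) {
    M <- do.call(cbind, tr[ts$channels])
    if (demean) M <- sweep(M, 2, colMeans(M))
    M
  })
  n <- length(ts$channels)
  fit1 <- function(r) {
    XY <- build_var_regressors(trials, r)
    XtX <- crossprod(XY$X)
    if (rcond(XtX) < 1e-14) stop("ill-conditioned regressor matrix at order ", r)
    B <- solve(XtX, crossprod(XY$X, XY$Y))       # (n*r) x n
    E <- XY$Y - XY$X %*% B
    N <- nrow(XY$Y)
    Sig <- crossprod(E) / (N - n * r)
    ll_sig <- crossprod(E) / N
    icv <- log(det(ll_sig)) + (if (ic == "aic") 2 else log(N)) * (r * n^2) / N
    list(B = B, Sigma = Sig, ic = icv, N = N)
  }
  orders <- sort(unique(as.integer(order)))
  fits <- lapply(orders, fit1)
  best <- which.min(vapply(fits, `[[`, numeric(1), "ic"))
  r <- orders[best]
  B <- fits[[best]]$B
  coeffs <- lapply(seq_len(r), function(k) t(B[((k - 1) * n + 1):(k * n), , drop = FALSE]))
  m <- var_model(coeffs, fs = fs, noise_cov = fits[[best]]$Sigma,
                 channels = ts$channels)
  m$residual_cov <- fits[[best]]$Sigma
  m$selected_order <- r
  m$ic_table <- data.frame(order = orders,
                           ic = vapply(fits, `[[`, numeric(1), "ic"))
  m
}

build_var_regressors <- function(trials, r) {
  Xs <- list(); Ys <- list()
  for (M in trials) {
    N <- nrow(M)
    if (N <= r) stop("trial shorter than the model order")
    idx <- (r + 1):N
    Ys[[length(Ys) + 1]] <- M[idx, , drop = FALSE]
    Xs[[length(Xs) + 1]] <- do.call(cbind, lapply(seq_len(r), function(k)
      M[idx - k, , drop = FALSE]))
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

#' Mixed-frequency VAR Granger causality test
#'
#' Stacks the m within-period samples of the fast channel with the
#' contemporaneous slow sample into one vector on the slow clock
#' (`Theta_t = [xH(t,1), ..., xH(t,m), xL(t)]`, m = rate ratio), fits a
#' VAR(order) by multi-trial least squares, and tests each direction by a
#' joint Wald zero-restriction on the relevant cross-coefficient block
#' against a chi-squared reference distribution: fast -> slow restricts the
#' fast-lag coefficients in the slow equation; slow -> fast restricts the
#' slow-lag coefficients in all fast equations.
#'
#' @param ts a [timeseries_set].
#' @param x fast (high-rate) channel name.
#' @param y slow (low-rate) channel name.
#' @param order VAR order on the slow clock.
#' @return a list with per-direction Wald statistics, degrees of freedom and
#'   p-values, plus the stacked-model dimensions.
#' @export
mf_var_gc <- function(ts, x, y, order = 1) {
  m <- ts$fs[[x]] / ts$fs[[y]]
  if (abs(m - round(m)) > 1e-8) stop("rate ratio must be an integer")
  m <- as.integer(round(m))
  trials <- lapply(seq_len(n_trials(ts)), function(i) {
    xh <- ts$data[[i]][[x]]
    xl <- ts$data[[i]][[y]]
    nL <- min(length(xl), length(xh) %/% m)
    M <- matrix(0, nL, m + 1)
    for (j in seq_len(m)) M[, j] <- xh[(seq_len(nL) - 1) * m + j]
    M[, m + 1] <- xl[seq_len(nL)]
    sweep(M, 2, colMeans(M))
  })
  d <- m + 1
  XY <- build_var_regressors(trials, order)
  XtX <- crossprod(XY$X)
  if (rcond(XtX) < 1e-12) stop("singular stacked-regressor matrix")
  G <- solve(XtX)
  B <- G %*% crossprod(XY$X, XY$Y)             # (d*order) x d
  E <- XY$Y - XY$X %*% B
  N <- nrow(XY$Y)
  Sig <- crossprod(E) / (N - d * order)
  # regressor column layout: lag k block has columns (k-1)*d + (1..d)
  hf_cols <- unlist(lapply(seq_len(order), function(k) (k - 1) * d + seq_len(m)))
  lf_cols <- (seq_len(order) - 1L) * d + d
  wald <- function(rows, eqs) {
    b <- as.vector(B[rows, eqs, drop = FALSE])
    V <- kronecker(Sig[eqs, eqs, drop = FALSE], G[rows, rows, drop = FALSE])
    stat <- drop(t(b) %*% solve(V, b))
    df <- length(b)
    list(stat = stat, df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  list(x_to_y = wald(hf_cols, d),
       y_to_x = wald(lf_cols, seq_len(m)),
       m = m, order = order, stacked_dim = d, n_obs = N,
       residual_cov = Sig)
}
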