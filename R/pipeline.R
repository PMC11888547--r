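#' Phase-randomized surrogate data
#'
#' Per trial and channel: forward Fourier transform, replacement of the
#' phases by i.i.d. uniform phases respecting conjugate symmetry (DC and
#' Nyquist bins kept real), inverse transform. The amplitude spectrum - and
#' hence the autocovariance - of every channel is preserved exactly, while
#' all temporal regularity between channels is destroyed. This is the null
#' model for the canonical-correlation significance tests.
#'
#' @param ts a [timeseries_set].
#' @param seed RNG seed.
#' @export
phase_randomize <- function(ts, seed) {
  set.seed(seed)
  data <- lapply(ts$data, function(tr) lapply(tr, phase_randomize_vec))
  timeseries_set(data, ts$fs)
}

phase_randomize_vec <- function(x) {
  n <- length(x)
  F <- stats::fft(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  if (half > 0) {
    ph <- exp(2i * pi * stats::runif(half))
    idx <- 2:(half + 1)
    F[idx] <- F[idx] * ph
    F[n + 2 - idx] <- Conj(F[idx])
  }
  Re(stats::fft(F, inverse = TRUE)) / n
}

#' MF-TFCCA: lagged canonical correlation between mixed-frequency series
#'
#' The core estimator of directed spectral information flow. The fast
#' channel `x` is converted to a time-frequency representation by a
#' moving-window STFT aligned to the slow channel's clock and z-scored per
#' frequency; the canonical correlation between the TFR and the slow
#' channel `y` is then computed at every signed lag on the slow sample
#' grid, per trial, and averaged. Large canonical correlation at negative
#' lags (the TFR history preceding `y`) is evidence for x -> y information
#' flow; at positive lags, for y -> x. A phase-randomization surrogate
#' ensemble provides the per-lag null envelope (for display) and the
#' direction call: a side is declared when the maximum of the observed
#' profile beyond the window-length boundary on that side exceeds the
#' corresponding quantile of the surrogate side-maximum (a max-statistic
#' correction for the many correlated lags).
#'
#' @param ts a [timeseries_set].
#' @param x fast channel name (its rate must be >= the slow channel's).
#' @param y slow channel name.
#' @param z optional conditioning channel for partial CCA (see `z_role`).
#' @param window_len STFT window length in seconds.
#' @param lag_range lag span in seconds, `c(min, max)` (default +-0.5 s).
#' @param mode `"complex"` (complex CCA, magnitude of the weights reported)
#'   or `"magnitude"` (CCA on the TFR modulus). The magnitude mode detects
#'   couplings carried in spectral power, e.g. phase-amplitude coupling.
#' @param n_surrogates surrogate pairs for the null envelope (default 100;
#'   0 skips the surrogate stage and no direction is called).
#' @param reg ridge regularization for the CCA (see [cca()]).
#' @param n_fft FFT length; default is the window length in samples (no
#'   zero padding), which keeps the CCA dimension at its natural value.
#' @param z_role `"raw"` (z sampled on the slow clock, conditioned as is)
#'   or `"tfr"` (z is a fast channel; its z-scored STFT is the conditioner).
#' @param window STFT taper, `"hann"` or `"rectangular"`.
#' @param conf_level envelope coverage (default 0.95).
#' @param seed seed for the surrogate ensemble.
#' @return an object of class `mftfcca` with the lag-CC profile, per-trial
#'   canonical correlations, surrogate envelope and direction call;
#'   see [print.mftfcca()], [plot.mftfcca()], [coef.mftfcca()],
#'   [summary.mftfcca()].
#' @export
mftfcca <- function(ts, x, y, z = NULL, window_len, lag_range = c(-0.5, 0.5),
                    mode = c("complex", "magnitude"), n_surrogates = 100,
                    reg = 1e-3, n_fft = NULL,
                    z_role = c("raw", "tfr"), window = "hann",
                    conf_level = 0.95, seed = 1) {
  mode <- match.arg(mode)
  z_role <- match.arg(z_role)
  if (ts$fs[[x]] < ts$fs[[y]]) stop("channel '", x, "' must have the higher rate")
  fs_y <- ts$fs[[y]]
  lags <- seq(ceiling(lag_range[1] * fs_y), floor(lag_range[2] * fs_y)) / fs_y
  cc_trials <- profile_cc(ts, x, y, z, window_len, lags, mode, reg, n_fft,
                          z_role, window)
  cc_mean <- colMeans(cc_trials)
  null_cc <- NULL; null_trials_peak <- NULL
  null_mean <- null_lo <- null_hi <- rep(NA_real_, length(lags))
  if (n_surrogates > 0) {
    null_cc <- matrix(NA_real_, n_surrogates, length(lags))
    for (s in seq_len(n_surrogates)) {
      sur <- phase_randomize(ts, seed = seed + s)
      sc <- profile_cc(sur, x, y, z, window_len, lags, mode, reg, n_fft,
                       z_role, window)
      null_cc[s, ] <- colMeans(sc)
      if (s == 1) null_trials <- array(NA_real_, c(n_surrogates, dim(sc)))
      null_trials[s, , ] <- sc
    }
    a <- (1 - conf_level) / 2
    null_mean <- colMeans(null_cc)
    null_lo <- apply(null_cc, 2, stats::quantile, probs = a)
    null_hi <- apply(null_cc, 2, stats::quantile, probs = 1 - a)
    null_trials_peak <- null_trials
  }
  obj <- structure(list(
    lags = lags, cc = cc_mean, cc_trials = cc_trials,
    null_mean = null_mean, null_lo = null_lo, null_hi = null_hi,
    null_cc = null_cc, null_cc_trials = null_trials_peak,
    window_len = window_len, mode = mode, reg = reg, n_fft = n_fft,
    channels = c(x = x, y = y, z = if (is.null(z)) NA_character_ else z),
    z_role = if (is.null(z)) NA_character_ else z_role,
    fs = c(x = ts$fs[[x]], y = fs_y),
    n_trials = n_trials(ts), n_surrogates = n_surrogates,
    conf_level = conf_level, window = window, ts = ts),
    class = "mftfcca")
  obj$direction_call <- direction_call(obj)
  obj
}

# per-trial lag-CC matrix (trials x lags)
profile_cc <- function(ts, x, y, z, window_len, lags, mode, reg, n_fft,
                       z_role, window) {
  fs_y <- ts$fs[[y]]
  cmode <- if (mode == "complex") "complex_then_abs" else "abs_then_cca"
  tfrs <- zscore_tfr(stft_tfr(ts, x, window_len, target_fs = fs_y,
                              n_fft = n_fft, window = window))
  ytr <- ts_channel(ts, y)
  zmats <- build_conditioner(ts, z, z_role, window_len, n_fft, fs_y, ytr, window)
  nt <- n_trials(ts)
  cc <- matrix(NA_real_, nt, length(lags))
  for (i in seq_len(nt)) {
    for (j in seq_along(lags)) {
      cc[i, j] <- lagged_cca(tfrs[[i]], ytr[[i]], lag = lags[j], mode = cmode,
                             reg = reg, z = zmats[[i]])$cc
    }
  }
  cc
}

# conditioner per trial, indexed on the slow-channel sample grid (NA rows
# outside the TFR's aligned span are dropped during alignment)
build_conditioner <- function(ts, z, z_role, window_len, n_fft, fs_y, ytr,
                              window) {
  if (is.null(z)) return(vector("list", n_trials(ts)))
  if (z_role == "raw") {
    if (abs(ts$fs[[z]] - fs_y) > 1e-8)
      stop("z_role = 'raw' requires z on the slow channel's clock")
    return(lapply(ts_channel(ts, z), function(v) matrix(v, ncol = 1)))
  }
  ztfr <- zscore_tfr(stft_tfr(ts, z, window_len, target_fs = fs_y,
                              n_fft = n_fft, window = window))
  lapply(seq_len(n_trials(ts)), function(i) {
    tz <- ztfr[[i]]
    Z <- matrix(NA_complex_, length(ytr[[i]]), ncol(tz$values))
    rows <- seq_len(nrow(tz$values)) - 1 + tz$y_offset
    ok <- rows <= nrow(Z)
    Z[rows[ok], ] <- tz$values[ok, ]
    Z
  })
}

# A side is declared when the observed maximum of the lag-CC profile beyond
# the window-length boundary exceeds the (1+conf)/2 quantile of the surrogate
# side-maximum: the max statistic controls the family-wise error across the
# many correlated lags of a side, which a per-lag envelope does not.
direction_call <- function(obj) {
  if (obj$n_surrogates == 0 || is.null(obj$null_cc)) return(NA_character_)
  side_sig <- function(mask) {
    if (sum(mask) < 2) return(FALSE)
    null_max <- apply(obj$null_cc[, mask, drop = FALSE], 1, max)
    max(obj$cc[mask]) > stats::quantile(null_max, (1 + obj$conf_level) / 2)
  }
  xy <- side_sig(obj$lags < -obj$window_len)
  yx <- side_sig(obj$lags > obj$window_len)
  if (xy && yx) "bidirectional" else if (xy) "x_to_y" else if (yx) "y_to_x" else "none"
}

#' @export
print.mftfcca <- function(x, ...) {
  ch <- x$channels
  cat(sprintf("MF-TFCCA: %s (%g Hz) vs %s (%g Hz)%s, %d trials, window %g s, mode '%s'\n",
              ch[["x"]], x$fs[["x"]], ch[["y"]], x$fs[["y"]],
              if (!is.na(ch[["z"]])) paste0(" | ", ch[["z"]]) else "",
              x$n_trials, x$window_len, x$mode))
  pk <- peak_lags(x)
  if (!is.na(pk$neg_lag))
    cat(sprintf("  peak CC at negative lag: %.3f at %+.3f s (x -> y side)\n",
                pk$neg_cc, pk$neg_lag))
  if (!is.na(pk$pos_lag))
    cat(sprintf("  peak CC at positive lag: %.3f at %+.3f s (y -> x side)\n",
                pk$pos_cc, pk$pos_lag))
  cat(sprintf("  direction call: %s (%d surrogates)\n",
              ifelse(is.na(x$direction_call), "not assessed", x$direction_call),
              x$n_surrogates))
  invisible(x)
}

#' Peak lags of an MF-TFCCA profile
#'
#' Locates the maximum of the lag-CC curve on each side of zero (beyond the
#' window-length boundary) and overall.
#' @param object an `mftfcca` fit.
#' @export
peak_lags <- function(object) {
  lags <- object$lags; cc <- object$cc
  pick <- function(mask) {
    if (!any(mask)) return(c(NA_real_, NA_real_))
    i <- which(mask)[which.max(cc[mask])]
    c(lags[i], cc[i])
  }
  neg <- pick(lags <= -object$window_len)
  pos <- pick(lags >= object$window_len)
  all <- pick(rep(TRUE, length(lags)))
  list(neg_lag = neg[1], neg_cc = neg[2], pos_lag = pos[1], pos_cc = pos[2],
       peak_lag = all[1], peak_cc = all[2])
}

#' @export
summary.mftfcca <- function(object, test = c("t", "ks"), ...) {
  test <- match.arg(test)
  pk <- peak_lags(object)
  out <- list(fit = object, peaks = pk, test = test,
              p_neg = NA_real_, p_pos = NA_real_)
  if (object$n_surrogates > 0) {
    pval <- function(lag) {
      if (is.na(lag)) return(NA_real_)
      j <- which.min(abs(object$lags - lag))
      significance_test(object$cc_trials[, j],
                        as.vector(object$null_cc_trials[, , j]), test = test)
    }
    out$p_neg <- pval(pk$neg_lag)
    out$p_pos <- pval(pk$pos_lag)
  }
  class(out) <- "summary.mftfcca"
  out
}

#' @export
print.summary.mftfcca <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$p_neg))
    cat(sprintf("  x -> y peak: p = %.4g (%s-test vs surrogate null)\n", x$p_neg, x$test))
  if (!is.na(x$p_pos))
    cat(sprintf("  y -> x peak: p = %.4g (%s-test vs surrogate null)\n", x$p_pos, x$test))
  invisible(x)
}

#' @export
plot.mftfcca <- function(x, ...) {
  ylim <- range(0, x$cc, x$null_hi, na.rm = TRUE)
  graphics::plot(x$lags, x$cc, type = "l", col = "red", lwd = 2,
                 xlab = "lag (s)", ylab = "canonical correlation",
                 ylim = ylim, ...)
  if (!all(is.na(x$null_mean))) {
    graphics::polygon(c(x$lags, rev(x$lags)), c(x$null_lo, rev(x$null_hi)),
                      col = grDevices::adjustcolor("blue", 0.2), border = NA)
    graphics::lines(x$lags, x$null_mean, col = "blue")
  }
  graphics::abline(v = c(-1, 1) * x$window_len, lty = 2)
  invisible(x)
}

#' Per-frequency CCA coefficient magnitudes of a fit
#'
#' Recomputes the canonical weights at a chosen lag (default: the overall
#' profile peak) on a zero-padded frequency grid and returns the mean
#' coefficient magnitude per frequency across trials. This is the spectral
#' read-out of the driving frequency.
#'
#' @param object an `mftfcca` fit.
#' @param lag lag in seconds (default: overall peak lag).
#' @param n_fft padded FFT length; default `2^ceiling(log2(max(4 W, fs)))`.
#' @param measure `"loading"` (default) or `"weight"`, see
#'   [driving_frequency_report()].
#' @param ... unused.
#' @export
coef.mftfcca <- function(object, lag = NULL, n_fft = NULL,
                         measure = "loading", ...) {
  rep <- driving_frequency_report(object, peak_lag = lag, n_fft = n_fft,
                                  measure = measure)
  stats::setNames(rep$coef_magnitude, sprintf("%.3f", rep$freqs))
}

#' Driving-frequency report with filter-one-frequency-out attribution
#'
#' At the lag where the lag-CC profile peaks, recomputes the CCA on a finely
#' zero-padded frequency grid and reports the trial-averaged canonical
#' coefficient magnitude per frequency, its detected peaks (local maxima
#' above 50% of the global maximum after 3-bin smoothing, ties broken toward
#' lower frequency), and - for each requested band - the relative CC gain
#' `(cc_filtered - cc_original) / cc_original` after band-stopping the
#' source channel. A genuinely driving band gives a large negative gain.
#'
#' On a zero-padded grid the TFR columns are exactly collinear (the rank is
#' the window length), so the raw weight-vector modulus oscillates with the
#' window sidelobe period; the default `measure = "loading"` therefore
#' reports structure correlations (see [cca()]), which are invariant to the
#' collinearity and interpretable like principal-component coefficients.
#'
#' @param object an `mftfcca` fit.
#' @param peak_lag lag in seconds (default: the overall profile peak).
#' @param bands list of `c(low, high)` bands in Hz for the
#'   filter-one-frequency-out analysis (default: none).
#' @param n_fft padded FFT length for the frequency grid; default
#'   `2^ceiling(log2(max(4 W, fs)))` where W is the window in samples.
#' @param measure `"loading"` (default) or `"weight"` (`Mod(u)`).
#' @return an object of class `driving_freq_report`.
#' @export
driving_frequency_report <- function(object, peak_lag = NULL, bands = NULL,
                                     n_fft = NULL,
                                     measure = c("loading", "weight")) {
  measure <- match.arg(measure)
  if (!inherits(object, "mftfcca")) stop("expected an 'mftfcca' fit")
  ts <- object$ts
  x <- object$channels[["x"]]; y <- object$channels[["y"]]
  fs_x <- object$fs[["x"]]
  if (is.null(peak_lag)) peak_lag <- peak_lags(object)$peak_lag
  W <- round(object$window_len * fs_x)
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(max(4 * W, fs_x)))
  cmode <- if (object$mode == "complex") "complex_then_abs" else "abs_then_cca"
  run_at_lag <- function(tset) {
    tfrs <- zscore_tfr(stft_tfr(tset, x, object$window_len,
                                target_fs = object$fs[["y"]], n_fft = n_fft,
                                window = object$window))
    ytr <- ts_channel(tset, y)
    res <- lapply(seq_len(n_trials(tset)), function(i)
      lagged_cca(tfrs[[i]], ytr[[i]], lag = peak_lag, mode = cmode,
                 reg = object$reg))
    list(cc = mean(vapply(res, `[[`, numeric(1), "cc")),
         coef = rowMeans(vapply(res, function(r) {
           cm <- if (measure == "loading") r$loading else r$coef_magnitude
           cm / sqrt(sum(cm^2))
         }, numeric(length(res[[1]]$coef_magnitude)))),
         freqs = tfrs[[1]]$freqs)
  }
  base <- run_at_lag(ts)
  peaks <- find_coef_peaks(base$freqs, base$coef)
  gains <- NULL
  if (!is.null(bands)) {
    gains <- do.call(rbind, lapply(bands, function(b) {
      ccf <- run_at_lag(bandstop_filter(ts, x, b))$cc
      data.frame(low = b[1], high = b[2], cc = ccf,
                 cc_gain = (ccf - base$cc) / base$cc)
    }))
  }
  structure(list(freqs = base$freqs, coef_magnitude = base$coef,
                 peaks = peaks, cc = base$cc, cc_gain_per_band = gains,
                 peak_lag = peak_lag, n_fft = n_fft, measure = measure),
            class = "driving_freq_report")
}

# local maxima of the 3-bin smoothed magnitude above half the global max
find_coef_peaks <- function(freqs, mag) {
  n <- length(mag)
  sm <- mag
  if (n >= 3) sm <- stats::filter(mag, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- mag[is.na(sm)]
  sm <- as.numeric(sm)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) sm[i] > sm[i - 1] else TRUE
    right <- if (i < n) sm[i] >= sm[i + 1] else TRUE
    left && right
  }, logical(1))
  is_peak <- is_peak & sm >= 0.5 * max(sm)
  idx <- which(is_peak)
  idx <- idx[order(-sm[idx], freqs[idx])]
  data.frame(frequency = freqs[idx], magnitude = sm[idx])
}

#' @export
print.driving_freq_report <- function(x, ...) {
  cat(sprintf("Driving-frequency report at lag %+.3f s (grid step %.3g Hz)\n",
              x$peak_lag, x$freqs[2] - x$freqs[1]))
  if (nrow(x$peaks)) {
    cat("  coefficient peaks:\n")
    for (i in seq_len(min(5, nrow(x$peaks))))
      cat(sprintf("    %6.2f Hz  magnitude %.3f\n",
                  x$peaks$frequency[i], x$peaks$magnitude[i]))
  }
  if (!is.null(x$cc_gain_per_band)) {
    cat("  filter-one-frequency-out CC gains:\n")
    for (i in seq_len(nrow(x$cc_gain_per_band)))
      cat(sprintf("    [%g, %g] Hz: %+.1f%%\n", x$cc_gain_per_band$low[i],
                  x$cc_gain_per_band$high[i], 100 * x$cc_gain_per_band$cc_gain[i]))
  }
  invisible(x)
}

#' One-sided significance test of observed vs surrogate canonical correlations
#'
#' @param observed per-trial observed CC values.
#' @param null surrogate CC values (the null sample).
#' @param test `"t"` (Welch t-test) or `"ks"` (two-sample
#'   Kolmogorov-Smirnov); both one-sided for observed > null.
#' @return the p-value.
#' @export
significance_test <- function(observed, null, test = c("t", "ks")) {
  test <- match.arg(test)
  if (test == "t") {
    if (length(observed) < 2) stop("t-test needs >= 2 observed values")
    stats::t.test(observed, null, alternative = "greater")$p.value
  } else {
    if (length(observed) < 5 || length(null) < 5)
      stop("ks-test needs >= 5 samples per group")
    suppressWarnings(stats::ks.test(observed, null, alternative = "less")$p.value)
  }
}

#' Lagged normalized cross-correlation between two channels
#'
#' Computes `corr(x(t), y(t + lag))` on the fine (higher-rate) lag grid,
#' per trial, and averages across trials. For mixed rates each slow sample
#' is paired with the fast sample at the lagged fine-grid position.
#' Positive-lag peaks indicate that x precedes y.
#'
#' @param ts a [timeseries_set].
#' @param x,y channel names (x must have the higher or equal rate).
#' @param max_lag maximum absolute lag in seconds.
#' @return class `xcorr_profile`: `lags` (s), `cc` (trial-averaged
#'   correlations).
#' @export
xcorr_profile <- function(ts, x, y, max_lag) {
  fs_x <- ts$fs[[x]]; fs_y <- ts$fs[[y]]
  if (fs_x < fs_y) stop("channel '", x, "' must have the higher rate")
  K <- fs_x / fs_y
  if (abs(K - round(K)) > 1e-8) stop("rate ratio must be an integer")
  K <- as.integer(round(K))
  L <- round(max_lag * fs_x)
  xs <- ts_channel(ts, x); ys <- ts_channel(ts, y)
  if (L >= length(xs[[1]])) stop("max_lag exceeds the trial length")
  lag_samp <- (-L):L
  cc <- rowMeans(vapply(seq_along(xs), function(i) {
    xv <- xs[[i]]; yv <- ys[[i]]
    fine <- (seq_along(yv) - 1) * K + 1       # fine-grid index of each y sample
    vapply(lag_samp, function(m) {
      xi <- fine - m                          # y(t + m/fs_x) pairs x(t)
      ok <- xi >= 1 & xi <= length(xv)
      if (sum(ok) < 3) return(NA_real_)
      stats::cor(xv[xi[ok]], yv[ok])
    }, numeric(1))
  }, numeric(length(lag_samp))))
  structure(list(lags = lag_samp / fs_x, cc = cc, channels = c(x, y)),
            class = "xcorr_profile")
}

#' @export
print.xcorr_profile <- function(x, ...) {
  neg <- x$lags < 0; pos <- x$lags > 0
  i_n <- which(neg)[which.max(x$cc[neg])]
  i_p <- which(pos)[which.max(x$cc[pos])]
  cat(sprintf("Lagged cross-correlation %s vs %s\n", x$channels[1], x$channels[2]))
  cat(sprintf("  max at negative lag: %.3f at %+.3f s\n", x$cc[i_n], x$lags[i_n]))
  cat(sprintf("  max at positive lag: %.3f at %+.3f s\n", x$cc[i_p], x$lags[i_p]))
  invisible(x)
}

#' @export
plot.xcorr_profile <- function(x, ...) {
  graphics::plot(x$lags, x$cc, type = "l", xlab = "lag (s)",
                 ylab = "correlation", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
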