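#' Decimate one channel with anti-alias filtering
#'
#' Low-pass filters the channel below the new Nyquist frequency (zero-phase
#' Butterworth, cutoff 0.8 times the new Nyquist, effective order 8 via
#' forward-backward filtering) and keeps every `factor`-th sample.
#'
#' @param ts a [timeseries_set].
#' @param channel channel name.
#' @param factor integer decimation factor (>= 2).
#' @return a [timeseries_set] with the channel at `fs / factor`.
#' @export
decimate <- function(ts, channel, factor) {
  if (factor != round(factor) || factor < 2) stop("'factor' must be an integer >= 2")
  fs <- ts$fs[[channel]]
  new_fs <- fs / factor
  bf <- signal::butter(4, 0.8 * (new_fs / 2) / (fs / 2), type = "low")
  trials <- lapply(ts_channel(ts, channel), function(x) {
    xf <- signal::filtfilt(bf, x)
    xf[seq(1, length(x), by = factor)]
  })
  ts_replace_channel(ts, channel, trials, fs = new_fs)
}

#' Zero-phase band-stop filter on one channel
#'
#' Used by the filter-one-frequency-out attribution: removes a narrow band
#' from the source channel so the canonical correlation can be recomputed
#' without that band's contribution.
#'
#' @param ts a [timeseries_set].
#' @param channel channel name.
#' @param band numeric `c(low, high)` in Hz, inside (0, fs/2).
#' @export
bandstop_filter <- function(ts, channel, band) {
  fs <- ts$fs[[channel]]
  if (length(band) != 2 || band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(2, band / (fs / 2), type = "stop")
  trials <- lapply(ts_channel(ts, channel), function(x) signal::filtfilt(bf, x))
  ts_replace_channel(ts, channel, trials)
}

#' Short-time Fourier transform aligned to a low-frequency clock
#'
#' Computes the moving-window Fourier transform of a fast channel with hop
#' equal to one sample period of the slow target rate, so that each time bin
#' of the result corresponds to one sample of the slow channel (overlap =
#' window length - 1/target_fs). Windows are placed only where they fit
#' entirely inside the trial; each bin is indexed by the time of its window
#' center (the taper's center of mass), so bin k pairs with the nearest
#' slow-channel sample `k - 1 + round((W-1)/2/hop) + 1`. Zero lag therefore
#' means the window is centered on the slow sample, and a window fully in
#' the slow sample's past corresponds to lags beyond one window length.
#'
#' @param ts a [timeseries_set].
#' @param channel fast channel name.
#' @param window_len window length in seconds.
#' @param target_fs slow clock rate in Hz; `fs / target_fs` must be an integer.
#' @param n_fft FFT length; `NULL` (default) uses the window length
#'   (no zero padding). Larger values zero-pad for a finer frequency grid.
#' @param window taper shape, `"hann"` (default) or `"rectangular"`.
#' @return a list of `tfr` objects, one per trial; each has complex
#'   `values` (time bins x frequencies), `times`, `freqs`, `hop`,
#'   `y_offset` (1-based index of the slow sample aligned with bin 1).
#' @export
stft_tfr <- function(ts, channel, window_len, target_fs, n_fft = NULL,
                     window = c("hann", "rectangular")) {
  window <- match.arg(window)
  fs <- ts$fs[[channel]]
  if (target_fs > fs) stop("target_fs must not exceed the channel rate")
  hop <- fs / target_fs
  if (abs(hop - round(hop)) > 1e-8) stop("fs / target_fs must be an integer")
  hop <- as.integer(round(hop))
  W <- as.integer(round(window_len * fs))
  if (W < 2) stop("window too short: fewer than 2 samples")
  if (hop > W) stop("hop exceeds window length")
  if (is.null(n_fft)) n_fft <- W
  if (n_fft < W) stop("n_fft must be at least the window length in samples")
  taper <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(W) / (W + 1)) else rep(1, W)
  nfreq <- n_fft %/% 2 + 1
  freqs <- (seq_len(nfreq) - 1) * fs / n_fft
  lapply(ts_channel(ts, channel), function(x) {
    N <- length(x)
    if (W > N) stop("window longer than trial")
    nb <- (N - W) %/% hop + 1
    starts <- (seq_len(nb) - 1) * hop
    seg <- matrix(0, n_fft, nb)
    for (k in seq_len(nb)) seg[seq_len(W), k] <- x[starts[k] + seq_len(W)] * taper
    V <- stats::mvfft(seg)[seq_len(nfreq), , drop = FALSE]
    structure(list(values = t(V), times = (starts + (W + 1) / 2) / fs,
                   freqs = freqs,
                   source_fs = fs, target_fs = target_fs,
                   window_len = W / fs, hop = hop / fs,
                   y_offset = as.integer(round((W - 1) / 2 / hop) + 1)),
              class = "tfr")
  })
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("TFR: %d time bins x %d frequencies (0-%g Hz), window %g s, hop %g s\n",
              nrow(x$values), ncol(x$values), max(x$freqs), x$window_len, x$hop))
  invisible(x)
}

#' Per-frequency z-score normalization of a TFR
#'
#' Removes the complex mean of each frequency column and scales by the
#' standard deviation of the complex samples (a single real scale, so phase
#' is preserved). Zero-variance columns are left at zero with a warning.
#' Idempotent up to numerical tolerance. Accepts a single `tfr` or a list.
#'
#' @param tfr a `tfr` object or list of them (as returned by [stft_tfr()]).
#' @export
zscore_tfr <- function(tfr) {
  if (!inherits(tfr, "tfr")) return(lapply(tfr, zscore_tfr))
  V <- tfr$values
  mu <- colMeans(V)
  Vc <- sweep(V, 2, mu)
  s <- sqrt(colMeans(Mod(Vc)^2) * nrow(V) / max(1, nrow(V) - 1))
  zero <- s < .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " zero-variance frequency column(s) left at zero")
    s[zero] <- 1
  }
  tfr$values <- sweep(Vc, 2, s, "/")
  tfr
}

#' Magnitude of a TFR
#'
#' Elementwise modulus; the result is real-valued. Used by the magnitude
#' variant of MF-TFCCA, where causal information carried in spectral power
#' (e.g. phase-amplitude coupling) is recoverable while the complex variant
#' averages it out.
#'
#' @param tfr a `tfr` object or list of them.
#' @export
tfr_magnitude <- function(tfr) {
  if (!inherits(tfr, "tfr")) return(lapply(tfr, tfr_magnitude))
  tfr$values <- Mod(tfr$values)
  tfr
}
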