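#' Multi-trial, multichannel time-series container with per-channel rates
#'
#' A `timeseries_set` holds repeated trials of simultaneously recorded
#' channels, where each channel carries its own sampling rate. Channels with
#' equal rates must have equal sample counts within a trial; channels with
#' unequal rates must have sample counts in the ratio of their rates (up to
#' one sample, to accommodate filtering edge effects).
#'
#' @param data a list of trials; each trial is a named list of numeric
#'   vectors (one per channel), or a matrix with one column per channel when
#'   all channels share a rate.
#' @param fs named numeric vector of sampling rates (Hz), one per channel.
#' @return an object of class `timeseries_set`.
#' @export
timeseries_set <- function(data, fs) {
  if (is.null(names(fs)) || any(!nzchar(names(fs))))
    stop("'fs' must be a named vector of per-channel sampling rates")
  if (any(!is.finite(fs)) || any(fs <= 0))
    stop("sampling rates must be positive and finite")
  channels <- names(fs)
  data <- lapply(data, function(tr) {
    if (is.matrix(tr)) tr <- as.list(as.data.frame(tr))
    if (is.null(names(tr))) names(tr) <- channels[seq_along(tr)]
    if (!setequal(names(tr), channels))
      stop("trial channels do not match names(fs): ",
           paste(setdiff(channels, names(tr)), collapse = ", "))
    lapply(tr[channels], as.numeric)
  })
  obj <- structure(list(data = data, fs = fs, channels = channels),
                   class = "timeseries_set")
  validate_timeseries_set(obj)
  obj
}

validate_timeseries_set <- function(ts) {
  for (i in seq_along(ts$data)) {
    tr <- ts$data[[i]]
    n <- vapply(tr, length, integer(1))
    for (a in ts$channels) for (b in ts$channels) {
      expect_b <- n[[a]] * ts$fs[[b]] / ts$fs[[a]]
      tol <- max(1, ts$fs[[b]] / ts$fs[[a]])  # one slow sample of slack
      if (abs(n[[b]] - expect_b) > tol + 1e-8)
        stop(sprintf(
          "trial %d: channels '%s' (%d samples @ %g Hz) and '%s' (%d samples @ %g Hz) are not rate-consistent",
          i, a, n[[a]], ts$fs[[a]], b, n[[b]], ts$fs[[b]]))
    }
  }
  invisible(ts)
}

#' @export
print.timeseries_set <- function(x, ...) {
  cat("Mixed-frequency time-series set\n")
  cat("  trials  :", length(x$data), "\n")
  n1 <- if (length(x$data)) vapply(x$data[[1]], length, integer(1)) else integer(0)
  for (ch in x$channels)
    cat(sprintf("  %-8s %g Hz, %d samples/trial\n", ch, x$fs[[ch]],
                if (length(n1)) n1[[ch]] else 0L))
  invisible(x)
}

#' Number of trials in a timeseries_set
#' @param ts a `timeseries_set`.
#' @export
n_trials <- function(ts) length(ts$data)

#' Extract one channel as a list of per-trial vectors
#' @param ts a `timeseries_set`.
#' @param channel channel name.
#' @export
ts_channel <- function(ts, channel) {
  if (!channel %in% ts$channels) stop("unknown channel: ", channel)
  lapply(ts$data, `[[`, channel)
}

#' Keep a subset of channels
#' @param ts a `timeseries_set`.
#' @param channels channel names to keep.
#' @export
ts_select <- function(ts, channels) {
  timeseries_set(lapply(ts$data, `[`, channels), ts$fs[channels])
}

#' Replace one channel's per-trial data (and optionally its rate)
#' @param ts a `timeseries_set`.
#' @param channel channel name.
#' @param trials list of per-trial numeric vectors.
#' @param fs new sampling rate; defaults to the channel's current rate.
#' @export
ts_replace_channel <- function(ts, channel, trials, fs = ts$fs[[channel]]) {
  if (length(trials) != n_trials(ts)) stop("trial count mismatch")
  data <- ts$data
  for (i in seq_along(data)) data[[i]][[channel]] <- as.numeric(trials[[i]])
  newfs <- ts$fs
  newfs[[channel]] <- fs
  timeseries_set(data, newfs)
}
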