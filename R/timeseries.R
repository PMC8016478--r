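#' Construct a regularly sampled time series
#'
#' Lightweight container for a single-channel voltage trace (LFP, membrane
#' potential, or any derived signal such as a band envelope).
#'
#' @param samples Numeric vector of sample values.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `so_ts`: a numeric vector with `fs` and `t0`
#'   attributes.
#' @export
so_ts <- function(samples, fs, t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("samples must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  structure(as.numeric(samples), fs = as.numeric(fs), t0 = as.numeric(t0),
            class = "so_ts")
}

#' @export
print.so_ts <- function(x, ...) {
  cat(sprintf("<so_ts> %d samples @ %g Hz, t0 = %g s, duration = %g s\n",
              length(x), ts_fs(x), ts_t0(x), ts_duration(x)))
  invisible(x)
}

#' Sampling rate, start time and duration of a time series
#' @param x An `so_ts` object.
#' @return `ts_fs`: sampling rate (Hz); `ts_t0`: start time (s);
#'   `ts_duration`: duration (s); `ts_time`: vector of sample times (s).
#' @export
ts_fs <- function(x) attr(x, "fs")

#' @rdname ts_fs
#' @export
ts_t0 <- function(x) attr(x, "t0")

#' @rdname ts_fs
#' @export
ts_duration <- function(x) length(x) / ts_fs(x)

#' @rdname ts_fs
#' @export
ts_time <- function(x) ts_t0(x) + (seq_along(x) - 1) / ts_fs(x)

# rebuild an so_ts with the same timebase but new samples
ts_like <- function(samples, template) {
  so_ts(samples, fs = ts_fs(template), t0 = ts_t0(template))
}

check_band <- function(low_hz, high_hz, fs) {
  nyq <- fs / 2
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < nyq))
    stop(sprintf(
      "invalid band [%g, %g] Hz: need 0 < low < high < Nyquist (%g Hz)",
      low_hz, high_hz, nyq))
  invisible(TRUE)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 3rd-order Butterworth applied forward and backward (zero phase), so event
#' boundaries detected on the filtered trace are not lag-shifted.
#'
#' @param x An `so_ts` object.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param order Filter order (per pass); default 3.
#' @return Filtered `so_ts` with the same length and timebase.
#' @export
so_bandpass <- function(x, low_hz, high_hz, order = 3) {
  stopifnot(inherits(x, "so_ts"))
  fs <- ts_fs(x)
  check_band(low_hz, high_hz, fs)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  ts_like(as.numeric(signal::filtfilt(bf, as.numeric(x))), x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' @param x An `so_ts` object.
#' @param cutoff_hz Cutoff frequency in Hz (below Nyquist).
#' @param order Filter order (per pass); default 3.
#' @return Filtered `so_ts` with the same length and timebase.
#' @export
so_lowpass <- function(x, cutoff_hz, order = 3) {
  stopifnot(inherits(x, "so_ts"))
  fs <- ts_fs(x)
  if (!(cutoff_hz > 0 && cutoff_hz < fs / 2))
    stop(sprintf("invalid cutoff %g Hz: need 0 < cutoff < Nyquist (%g Hz)",
                 cutoff_hz, fs / 2))
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  ts_like(as.numeric(signal::filtfilt(bf, as.numeric(x))), x)
}

#' Amplitude envelope of a band-passed signal
#'
#' Band-passes the trace (default 50-250 Hz, the gamma band used to confirm
#' upstates in single-cell recordings) and returns the magnitude of its
#' analytic signal.
#'
#' @inheritParams so_bandpass
#' @return Non-negative `so_ts` envelope, same length as the input.
#' @export
so_envelope <- function(x, low_hz = 50, high_hz = 250, order = 3) {
  xb <- so_bandpass(x, low_hz, high_hz, order = order)
  ts_like(analytic_magnitude(as.numeric(xb)), x)
}

# |analytic signal| via FFT: zero out negative frequencies, double positive
analytic_magnitude <- function(v) {
  n <- length(v)
  if (n == 1L) return(abs(v))
  f <- stats::fft(v)
  u <- numeric(n)
  u[1] <- 1
  if (n %% 2 == 0) {
    u[n / 2 + 1] <- 1
    u[2:(n / 2)] <- 2
  } else {
    u[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(f * u, inverse = TRUE) / n)
}

#' Centered moving median
#'
#' Running median with a centered window; within the first and last
#' half-windows the nearest full-window median is carried to the edge
#' (constant extension), so no data is fabricated and the rule stays cheap
#' for windows of tens of seconds at kilohertz rates. Used as the dynamic
#' baseline `m` of the upstate detector, where it absorbs slow
#' non-stationarities that a moving mean would track poorly.
#'
#' @param x An `so_ts` object.
#' @param window_s Window length in seconds (default 60).
#' @return `so_ts` of the same length.
#' @export
moving_median <- function(x, window_s = 60) {
  stopifnot(inherits(x, "so_ts"))
  n <- length(x)
  if (n == 0L) stop("empty input")
  k <- round(window_s * ts_fs(x))
  if (k %% 2 == 0) k <- k + 1
  if (k > n) k <- n - (1 - n %% 2)
  if (k < 3) return(ts_like(as.numeric(x), x))
  m <- as.numeric(stats::runmed(as.numeric(x), k, endrule = "keep"))
  h <- (k - 1) / 2
  if (h >= 1) {
    # constant extension: carry the first/last full-window median outward
    m[seq_len(h)] <- m[h + 1]
    m[(n - h + 1):n] <- m[n - h]
  }
  ts_like(m, x)
}

#' Population spike rate in contiguous windows
#'
#' Pools spikes across all units and bins them into contiguous,
#' non-overlapping windows (default 100 ms), returning the summed rate in
#' spikes/s per window.
#'
#' @param trains List of numeric vectors of spike times (seconds).
#' @param window_s Window length in seconds (default 0.1).
#' @param t_start,t_end Span covered by the windows; spikes outside
#'   `[t_start, t_end)` are ignored.
#' @return A data frame of class `so_poprate` with columns `t` (window start,
#'   s) and `rate` (spikes/s), and a `window_s` attribute.
#' @export
population_rate <- function(trains, window_s = 0.1, t_start = 0, t_end) {
  stopifnot(is.list(trains), window_s > 0, t_end > t_start)
  all_t <- unlist(trains, use.names = FALSE)
  if (length(all_t) && any(all_t < 0)) stop("negative spike times")
  n_win <- ceiling((t_end - t_start) / window_s)
  counts <- numeric(n_win)
  if (length(all_t)) {
    keep <- all_t >= t_start & all_t < t_start + n_win * window_s
    idx <- floor((all_t[keep] - t_start) / window_s) + 1
    counts <- tabulate(idx, nbins = n_win)
  }
  out <- data.frame(t = t_start + (seq_len(n_win) - 1) * window_s,
                    rate = counts / window_s)
  attr(out, "window_s") <- window_s
  class(out) <- c("so_poprate", "data.frame")
  out
}

#' Mean and standard deviation over a baseline window
#'
#' @param x An `so_ts` or `so_poprate` object.
#' @param window Two-element numeric `c(start_s, end_s)`.
#' @return List with `mean`, `sd`, and `window`.
#' @export
baseline_stats <- function(x, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  if (inherits(x, "so_poprate")) {
    sel <- x$t >= window[1] & x$t < window[2]
    v <- x$rate[sel]
  } else {
    tm <- ts_time(x)
    v <- as.numeric(x)[tm >= window[1] & tm < window[2]]
  }
  if (!length(v)) stop("baseline window contains no samples")
  list(mean = mean(v), sd = stats::sd(v), window = window)
}

#' Band power via Welch's method
#'
#' Integrates the one-sided Welch power spectral density (Hann window,
#' default 4 s segments, 50% overlap) over a frequency band. Frequencies are
#' assigned to the half-open band `(low, high]` so that disjoint bands sum
#' to the power of their union.
#'
#' @param x An `so_ts` object.
#' @param band_hz Two-element numeric `c(low, high)` in Hz.
#' @param epoch Optional `c(start_s, end_s)` restricting the analysis.
#' @param seg_s Welch segment length in seconds (default 4).
#' @param overlap Segment overlap fraction (default 0.5).
#' @return Scalar band power (signal units squared).
#' @export
band_power <- function(x, band_hz, epoch = NULL, seg_s = 4, overlap = 0.5) {
  stopifnot(inherits(x, "so_ts"), length(band_hz) == 2)
  fs <- ts_fs(x)
  if (band_hz[2] > fs / 2 + 1e-9)
    stop(sprintf("band edge %g Hz exceeds Nyquist (%g Hz)", band_hz[2], fs / 2))
  v <- as.numeric(x)
  if (!is.null(epoch)) {
    tm <- ts_time(x)
    if (epoch[1] < tm[1] - 1e-9 || epoch[2] > tm[length(tm)] + 1 / fs + 1e-9)
      stop("epoch outside recording")
    v <- v[tm >= epoch[1] & tm < epoch[2]]
  }
  n <- length(v)
  L <- min(n, round(seg_s * fs))
  if (L < 8) stop("epoch too short for spectral estimation")
  step <- max(1, floor(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  norm <- fs * sum(w^2)
  nfreq <- floor(L / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- v[s:(s + L - 1)] * w
    p <- Mod(stats::fft(seg))^2 / norm
    psd <- p[seq_len(nfreq)]
    # one-sided: double everything except DC (and Nyquist when L even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (L %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + psd * dbl
  }
  psd <- acc / length(starts)
  freq <- (seq_len(nfreq) - 1) * fs / L
  df <- fs / L
  sum(psd[freq > band_hz[1] & freq <= band_hz[2]]) * df
}

#' Select the detection channel by baseline variability
#'
#' Returns the channel with the highest standard deviation during the
#' baseline window: larger voltage deflections improve detection accuracy,
#' and slow oscillations are near-synchronous across channels so spatial
#' position is not otherwise weighted. Ties break to the lowest index.
#'
#' @param lfp Numeric matrix, samples x channels.
#' @param fs Sampling rate in Hz.
#' @param baseline_window `c(start_s, end_s)` relative to the first sample.
#' @return Integer channel index.
#' @export
select_detection_channel <- function(lfp, fs, baseline_window = c(0, 300)) {
  stopifnot(is.matrix(lfp), ncol(lfp) >= 1, fs > 0)
  i0 <- max(1L, floor(baseline_window[1] * fs) + 1L)
  i1 <- min(nrow(lfp), ceiling(baseline_window[2] * fs))
  if (i1 <= i0) stop("invalid baseline window")
  sds <- apply(lfp[i0:i1, , drop = FALSE], 2, stats::sd)
  which.max(sds)  # which.max returns the first (lowest) index on ties
}
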