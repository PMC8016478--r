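#' Unit quality control
#'
#' A unit passes when (1) the fraction of inter-spike intervals shorter than
#' the refractory period (2 ms) is below 5%, and (2) the estimated fraction
#' of spikes lost below the detection threshold is below 15%. The missing
#' fraction is the mass of a Gaussian fitted to the spike-amplitude
#' histogram that lies below the smallest observed amplitude; fitting the
#' histogram (least squares) rather than matching moments recovers the
#' underlying Gaussian even when the amplitude distribution is truncated by
#' the detection threshold.
#'
#' @param spike_times_s Numeric vector of spike times (s), sorted.
#' @param amplitudes Numeric vector of per-spike amplitudes (same length).
#' @param refractory_ms Refractory period (default 2).
#' @param max_violation Maximum tolerated violation fraction (default 0.05).
#' @param max_missing Maximum tolerated missing-spike fraction (default 0.15).
#' @param min_spikes Minimum spike count for a meaningful amplitude fit
#'   (default 50).
#' @return List with `pass` (logical), `violation_frac`, `missing_frac`,
#'   and `reason` (`"ok"`, `"too_few_spikes"`, `"refractory"`, `"missing"`,
#'   or `"refractory+missing"`).
#' @export
qc_unit <- function(spike_times_s, amplitudes, refractory_ms = 2,
                    max_violation = 0.05, max_missing = 0.15,
                    min_spikes = 50) {
  n <- length(spike_times_s)
  stopifnot(length(amplitudes) == n)
  if (n < min_spikes)
    return(list(pass = FALSE, violation_frac = NA_real_,
                missing_frac = NA_real_, reason = "too_few_spikes"))
  isi <- diff(sort(spike_times_s))
  viol <- if (length(isi)) mean(isi < refractory_ms / 1000) else 0
  miss <- missing_spike_fraction(amplitudes)
  bad <- c("refractory"[viol >= max_violation], "missing"[miss >= max_missing])
  list(pass = length(bad) == 0, violation_frac = viol, missing_frac = miss,
       reason = if (length(bad)) paste(bad, collapse = "+") else "ok")
}

# Gaussian fit to the amplitude histogram; returns the fitted mass below the
# minimum observed amplitude.  Least-squares on histogram counts so a
# threshold-truncated distribution still yields the un-truncated Gaussian.
missing_spike_fraction <- function(amplitudes) {
  n <- length(amplitudes)
  nb <- max(10L, ceiling(sqrt(n)))
  h <- graphics::hist(amplitudes, breaks = nb, plot = FALSE)
  xs <- h$mids
  ys <- h$counts
  mu0 <- mean(amplitudes)
  sd0 <- stats::sd(amplitudes)
  if (!is.finite(sd0) || sd0 <= 0) return(0)
  obj <- function(p) {
    a <- exp(p[1]); mu <- p[2]; s <- exp(p[3])
    sum((ys - a * exp(-(xs - mu)^2 / (2 * s^2)))^2)
  }
  fit <- stats::optim(c(log(max(ys)), mu0, log(sd0)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  mu <- fit$par[2]
  s <- exp(fit$par[3])
  stats::pnorm(min(amplitudes), mean = mu, sd = s)
}

#' Trough-to-peak latency and repolarization time of a mean waveform
#'
#' The trough-to-peak (TP) latency is the time from the global negative
#' trough to the subsequent global maximum; the repolarization time is the
#' time for that peak to decay to half its amplitude.
#'
#' @param waveform Numeric vector, the mean spike waveform; must have a
#'   negative global trough followed by at least one sample.
#' @param fs Sampling rate in Hz.
#' @return List with `tp_latency_ms` and `repolarization_time_ms` (the
#'   latter `NA` when the waveform ends before half-decay).
#' @export
waveform_features <- function(waveform, fs) {
  stopifnot(is.numeric(waveform), length(waveform) > 2, fs > 0)
  trough <- which.min(waveform)
  if (waveform[trough] >= 0)
    stop("waveform has no negative trough")
  if (trough >= length(waveform))
    stop("trough at waveform end: no post-trough peak, feature undefined")
  post <- waveform[(trough + 1):length(waveform)]
  peak <- trough + which.max(post)
  tp_ms <- (peak - trough) / fs * 1000
  amp <- waveform[peak]
  rep_ms <- NA_real_
  if (peak < length(waveform)) {
    below <- which(waveform[(peak + 1):length(waveform)] <= amp / 2)
    if (length(below)) rep_ms <- below[1] / fs * 1000
  }
  list(tp_latency_ms = tp_ms, repolarization_time_ms = rep_ms)
}

#' Classify a unit as putative excitatory or inhibitory
#'
#' Excitatory iff the trough-to-peak latency exceeds 0.55 ms, inhibitory if
#' below; an exact tie is assigned to `Int` (documented convention so the
#' rule is deterministic).
#'
#' @param tp_latency_ms Trough-to-peak latency in ms.
#' @param cutoff_ms Classification boundary (default 0.55).
#' @return `"Exc"` or `"Int"`.
#' @export
classify_unit_type <- function(tp_latency_ms, cutoff_ms = 0.55) {
  stopifnot(is.finite(tp_latency_ms), tp_latency_ms > 0)
  if (tp_latency_ms > cutoff_ms) "Exc" else "Int"
}

#' Configuration for drug-response classification
#'
#' @param eval_window_min Evaluation window after injection, minutes
#'   (default 25).
#' @param sustain_min Minimum suprathreshold time, minutes (default 5).
#' @param k_sigma Rate threshold in baseline SDs (default 2).
#' @param rate_bin_s Rate bin width, seconds (default 60).
#' @param baseline_min Baseline window before injection, minutes (default 10).
#' @return List of class `so_response_config`.
#' @export
response_config <- function(eval_window_min = 25, sustain_min = 5,
                            k_sigma = 2, rate_bin_s = 60, baseline_min = 10) {
  if (sustain_min > eval_window_min)
    stop("invalid field sustain_min: must be <= eval_window_min")
  structure(list(eval_window_min = eval_window_min, sustain_min = sustain_min,
                 k_sigma = k_sigma, rate_bin_s = rate_bin_s,
                 baseline_min = baseline_min),
            class = "so_response_config")
}

#' Classify a unit's drug response
#'
#' A unit is "activated" when its firing rate in the 25 min following drug
#' injection is more than `k_sigma` baseline SDs above the baseline mean for
#' a cumulative total of at least `sustain_min` minutes (bins need not be
#' consecutive). Rates are binned at `rate_bin_s`; the baseline is the
#' `baseline_min` minutes preceding the injection.
#'
#' @param spike_times_s Numeric vector of spike times (s).
#' @param injection_time_s Drug injection time (s).
#' @param cfg A [response_config()].
#' @return List with `response` (`"activated"` / `"non-activated"`),
#'   `suprathreshold_min`, `baseline_mean`, `baseline_sd`, and `degenerate`
#'   (TRUE when the baseline SD is zero while rates are nonzero).
#' @export
classify_drug_response <- function(spike_times_s, injection_time_s,
                                   cfg = response_config()) {
  bw <- cfg$rate_bin_s
  b0 <- injection_time_s - cfg$baseline_min * 60
  if (b0 < -1e-9)
    stop("recording does not span the baseline window before injection")
  base_edges <- seq(b0, injection_time_s, by = bw)
  eval_edges <- seq(injection_time_s,
                    injection_time_s + cfg$eval_window_min * 60, by = bw)
  bin_rates <- function(edges) {
    counts <- tabulate(findInterval(spike_times_s, edges,
                                    rightmost.closed = FALSE),
                       nbins = length(edges))[seq_len(length(edges) - 1)]
    counts / bw
  }
  base_r <- bin_rates(base_edges)
  eval_r <- bin_rates(eval_edges)
  mu <- mean(base_r)
  sig <- stats::sd(base_r)
  degenerate <- (sig == 0) && any(c(base_r, eval_r) > 0)
  supra_min <- sum(eval_r > mu + cfg$k_sigma * sig) * bw / 60
  list(response = if (supra_min >= cfg$sustain_min) "activated"
       else "non-activated",
       suprathreshold_min = supra_min, baseline_mean = mu, baseline_sd = sig,
       degenerate = degenerate)
}

#' Cohort summary of drug responses and waveform classes
#'
#' @param units Data frame with columns `response` (`"activated"` /
#'   `"non-activated"`), `class` (`"Exc"`/`"Int"`), `tp_latency_ms`.
#' @return List with `n_activated`, `n_total`, `fraction`, per-group mean TP
#'   latency, and per-group empirical cumulative distribution functions of
#'   TP latency (`ecdf` objects).
#' @export
response_population_summary <- function(units) {
  stopifnot(all(c("response", "class", "tp_latency_ms") %in% names(units)))
  act <- units$response == "activated"
  groups <- list(Exc = units$tp_latency_ms[units$class == "Exc" & !act],
                 Int = units$tp_latency_ms[units$class == "Int" & !act],
                 activated = units$tp_latency_ms[act])
  list(n_activated = sum(act), n_total = nrow(units),
       fraction = if (nrow(units)) sum(act) / nrow(units) else NA_real_,
       mean_tp_ms = lapply(groups, function(g) if (length(g)) mean(g)
                           else NA_real_),
       tp_ecdf = lapply(groups, function(g) if (length(g)) stats::ecdf(g)
                        else NULL))
}
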