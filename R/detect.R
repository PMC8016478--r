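#' Configuration for the dual-signal upstate detector
#'
#' All defaults are the values used throughout the package's analyses:
#' dynamic thresholds `a = m + k_a * sigma` and `b = m + k_b * sigma` on the
#' delta-band trace (where `m` is a 60 s centered moving median and `sigma`
#' the baseline standard deviation of the same trace), deletion of candidates
#' shorter than 200 ms, merging of candidates closer than 300 ms, splitting
#' at dips below `b`, and confirmation by population spiking exceeding its
#' baseline mean by 1 sigma in at least one 100 ms window.
#'
#' @param k_a Sigma multiplier for the candidate threshold `a` (default 1.5).
#' @param k_b Sigma multiplier for the splitting threshold `b` (default 0.8).
#' @param min_duration_s Minimum candidate duration in s (default 0.2).
#' @param merge_gap_s Candidates separated by less than this are joined
#'   (default 0.3).
#' @param pop_threshold_sigma Population-rate confirmation threshold in
#'   baseline SDs (default 1).
#' @param baseline_duration_s Length of the baseline window, from the start
#'   of the recording, used for all sigma estimates (default 300).
#' @param median_window_s Moving-median window (default 60).
#' @param delta_band_hz Detection band in Hz (default `c(0.5, 4)`).
#' @param pop_window_s Population-rate window (default 0.1).
#' @param invitro_baseline_s Baseline length for in vitro traces (default 60).
#' @param invitro_lowpass_hz Low-pass cutoff applied to each in vitro signal
#'   before thresholding (default 10, below the gamma band), so threshold
#'   crossings track the slow depolarization rather than fast synaptic
#'   fluctuations; 0 disables.
#' @return A list of class `so_detection_config`.
#' @export
detection_config <- function(k_a = 1.5, k_b = 0.8, min_duration_s = 0.2,
                             merge_gap_s = 0.3, pop_threshold_sigma = 1,
                             baseline_duration_s = 300, median_window_s = 60,
                             delta_band_hz = c(0.5, 4), pop_window_s = 0.1,
                             invitro_baseline_s = 60,
                             invitro_lowpass_hz = 10) {
  cfg <- list(k_a = k_a, k_b = k_b, min_duration_s = min_duration_s,
              merge_gap_s = merge_gap_s,
              pop_threshold_sigma = pop_threshold_sigma,
              baseline_duration_s = baseline_duration_s,
              median_window_s = median_window_s,
              delta_band_hz = delta_band_hz, pop_window_s = pop_window_s,
              invitro_baseline_s = invitro_baseline_s,
              invitro_lowpass_hz = invitro_lowpass_hz)
  validate_detection_config(cfg)
  class(cfg) <- "so_detection_config"
  cfg
}

validate_detection_config <- function(cfg) {
  if (!(cfg$k_a > cfg$k_b && cfg$k_b > 0))
    stop("invalid detection config: need k_a > k_b > 0")
  if (cfg$min_duration_s <= 0) stop("invalid field min_duration_s: must be > 0")
  if (cfg$merge_gap_s < 0) stop("invalid field merge_gap_s: must be >= 0")
  if (cfg$baseline_duration_s <= 0)
    stop("invalid field baseline_duration_s: must be > 0")
  invisible(cfg)
}

DUR_EPS <- 1e-9  # guard against float jitter in duration/gap comparisons

# runs of TRUE in a logical vector -> data.frame(start_idx, end_idx), inclusive
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

idx_to_sec <- function(cand_idx, fs, t0) {
  data.frame(start_s = t0 + (cand_idx$start_idx - 1) / fs,
             end_s = t0 + cand_idx$end_idx / fs)
}

sec_to_idx <- function(cand, fs, t0) {
  data.frame(start_idx = as.integer(round((cand$start_s - t0) * fs)) + 1L,
             end_idx = as.integer(round((cand$end_s - t0) * fs)))
}

#' Delete candidates shorter than a minimum duration
#'
#' Candidates strictly shorter than `min_duration_s` are removed; a candidate
#' of exactly the minimum duration is kept.
#'
#' @param candidates Data frame with `start_s` and `end_s` columns, sorted.
#' @param min_duration_s Minimum duration in seconds.
#' @return The filtered data frame.
#' @export
delete_short <- function(candidates, min_duration_s) {
  if (nrow(candidates) == 0) return(candidates)
  keep <- (candidates$end_s - candidates$start_s) >= min_duration_s - DUR_EPS
  candidates[keep, , drop = FALSE]
}

#' Merge candidates separated by small gaps
#'
#' Consecutive candidates whose gap is strictly less than `merge_gap_s` are
#' replaced by their union, applied transitively left to right until stable.
#'
#' @param candidates Sorted, non-overlapping data frame with `start_s`,
#'   `end_s`.
#' @param merge_gap_s Gap threshold in seconds.
#' @return Merged data frame.
#' @export
merge_close <- function(candidates, merge_gap_s) {
  n <- nrow(candidates)
  if (n <= 1) return(candidates)
  starts <- candidates$start_s
  ends <- candidates$end_s
  out_s <- starts[1]
  out_e <- ends[1]
  for (i in 2:n) {
    j <- length(out_e)
    if (starts[i] - out_e[j] < merge_gap_s - DUR_EPS) {
      out_e[j] <- max(out_e[j], ends[i])
    } else {
      out_s <- c(out_s, starts[i])
      out_e <- c(out_e, ends[i])
    }
  }
  data.frame(start_s = out_s, end_s = out_e)
}

# Split candidates at dips below threshold b.  A dip is a full excursion
# below b (down-crossing then up-crossing) strictly inside the candidate;
# each dip splits the candidate at the midpoint of its two crossings.
# Works on sample indices; returns indices.
split_candidates_idx <- function(cand_idx, x, b) {
  if (nrow(cand_idx) == 0) return(cand_idx)
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_len(nrow(cand_idx))) {
    s <- cand_idx$start_idx[i]
    e <- cand_idx$end_idx[i]
    seg_below <- x[s:e] < b[s:e]
    dips <- logical_runs(seg_below)
    # full dips only: below-b run must start after the candidate's first
    # sample and end before its last (down- then up-crossing inside)
    dips <- dips[dips$start_idx > 1 & dips$end_idx < (e - s + 1), , drop = FALSE]
    if (nrow(dips) == 0) {
      out_s <- c(out_s, s)
      out_e <- c(out_e, e)
      next
    }
    # crossing pair for a dip over samples [ds, de]: down-crossing at ds,
    # up-crossing at de + 1; midpoint in sample units
    mids <- (dips$start_idx + dips$end_idx + 1) / 2 + (s - 1)
    frag_start <- s
    for (m in mids) {
      left_end <- floor(m - DUR_EPS)
      out_s <- c(out_s, frag_start)
      out_e <- c(out_e, as.integer(left_end))
      frag_start <- as.integer(left_end) + 1L
    }
    out_s <- c(out_s, frag_start)
    out_e <- c(out_e, e)
  }
  data.frame(start_idx = out_s, end_idx = out_e)
}

#' Split a candidate at dips below the lower threshold
#'
#' If the detection signal inside a candidate crosses below the lower
#' threshold `b` and back above it, the candidate is split at the midpoint of
#' the two crossings; `n` dips produce `n` splits. Fragments are then
#' re-checked against the minimum duration by the caller.
#'
#' @param candidates Data frame with `start_s`, `end_s`.
#' @param signal `so_ts` detection signal.
#' @param b Numeric vector, the threshold trace (same length as `signal`).
#' @return Data frame of (possibly split) candidates.
#' @export
split_by_b <- function(candidates, signal, b) {
  stopifnot(inherits(signal, "so_ts"), length(b) == length(signal))
  fs <- ts_fs(signal)
  t0 <- ts_t0(signal)
  ci <- sec_to_idx(candidates, fs, t0)
  idx_to_sec(split_candidates_idx(ci, as.numeric(signal), b), fs, t0)
}

#' Confirm candidates against population spiking
#'
#' A candidate is confirmed iff at least one population-rate window with
#' nonzero time overlap has rate strictly above
#' `baseline mean + k * baseline sigma`.
#'
#' @param candidates Data frame with `start_s`, `end_s`.
#' @param pop `so_poprate` population activity.
#' @param pop_baseline List with `mean` and `sd` (from [baseline_stats()]),
#'   computed on the same baseline window as the LFP sigma.
#' @param k Sigma multiplier (default 1).
#' @return The confirmed subset of `candidates`.
#' @export
confirm_population <- function(candidates, pop, pop_baseline, k = 1) {
  if (nrow(candidates) == 0) return(candidates)
  win <- attr(pop, "window_s")
  thr <- pop_baseline$mean + k * pop_baseline$sd
  hot <- pop$rate > thr
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    ov <- pop$t < candidates$end_s[i] & (pop$t + win) > candidates$start_s[i]
    any(hot & ov)
  }, logical(1))
  candidates[keep, , drop = FALSE]
}

# area/peak of (x - m) clipped at zero over each event
event_measures <- function(cand, x, m, fs, t0) {
  ci <- sec_to_idx(cand, fs, t0)
  area <- numeric(nrow(ci))
  peak <- numeric(nrow(ci))
  for (i in seq_len(nrow(ci))) {
    seg <- x[ci$start_idx[i]:ci$end_idx[i]] - m[ci$start_idx[i]:ci$end_idx[i]]
    area[i] <- sum(pmax(seg, 0)) / fs
    peak[i] <- max(seg)
  }
  list(area = area, peak = peak)
}

make_events <- function(cand, x, m, fs, t0, confirmed = TRUE) {
  meas <- event_measures(cand, x, m, fs, t0)
  out <- data.frame(start_s = cand$start_s, end_s = cand$end_s,
                    duration_s = cand$end_s - cand$start_s,
                    area = meas$area, peak = meas$peak,
                    confirmed = confirmed)
  rownames(out) <- NULL
  class(out) <- c("so_upstates", "data.frame")
  out
}

empty_events <- function() {
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    duration_s = numeric(0), area = numeric(0),
                    peak = numeric(0), confirmed = logical(0))
  class(out) <- c("so_upstates", "data.frame")
  out
}

# candidate stages common to the in vivo and in vitro detectors:
# threshold at a, delete short, merge close, split by b, re-delete short
candidate_pipeline <- function(xd, m, sigma, cfg) {
  fs <- ts_fs(xd)
  t0 <- ts_t0(xd)
  x <- as.numeric(xd)
  a <- m + cfg$k_a * sigma
  b <- m + cfg$k_b * sigma
  cand <- idx_to_sec(logical_runs(x > a), fs, t0)
  cand <- delete_short(cand, cfg$min_duration_s)
  cand <- merge_close(cand, cfg$merge_gap_s)
  cand <- idx_to_sec(split_candidates_idx(sec_to_idx(cand, fs, t0), x, b),
                     fs, t0)
  delete_short(cand, cfg$min_duration_s)
}

#' Detect upstates in vivo from LFP and population spiking
#'
#' Runs the full dual-signal detector: (1) delta-band filter; (2) baseline
#' sigma and moving-median `m` of the filtered trace; (3) candidates as runs
#' above `a = m + k_a * sigma`; (4) deletion of candidates shorter than the
#' minimum duration; (5) merging of candidates closer than the merge gap;
#' (6) splitting at dips below `b = m + k_b * sigma`; (7) confirmation by
#' population spiking above its baseline mean + 1 sigma in at least one
#' overlapping window.
#'
#' @param lfp_channel `so_ts` raw LFP of the selected channel.
#' @param pop `so_poprate` population activity covering the recording.
#' @param cfg A [detection_config()].
#' @return Data frame of class `so_upstates` with columns `start_s`, `end_s`,
#'   `duration_s`, `area` (integral of the detection signal above `m`,
#'   signal-units x s), `peak`, `confirmed`.
#' @export
detect_upstates_invivo <- function(lfp_channel, pop, cfg = detection_config()) {
  stopifnot(inherits(lfp_channel, "so_ts"), inherits(pop, "so_poprate"))
  validate_detection_config(cfg)
  if (ts_duration(lfp_channel) < cfg$baseline_duration_s)
    stop("recording shorter than the baseline window")
  pop_end <- pop$t[nrow(pop)] + attr(pop, "window_s")
  if (pop_end < ts_t0(lfp_channel) + ts_duration(lfp_channel) - 1e-6)
    stop("population activity does not cover the recording")

  xd <- so_bandpass(lfp_channel, cfg$delta_band_hz[1], cfg$delta_band_hz[2])
  t0 <- ts_t0(xd)
  bw <- c(t0, t0 + cfg$baseline_duration_s)
  sigma <- baseline_stats(xd, bw)$sd
  m <- as.numeric(moving_median(xd, cfg$median_window_s))

  cand <- candidate_pipeline(xd, m, sigma, cfg)
  pop_base <- baseline_stats(pop, bw)
  cand <- confirm_population(cand, pop, pop_base, cfg$pop_threshold_sigma)
  if (nrow(cand) == 0) return(empty_events())
  make_events(cand, as.numeric(xd), m, ts_fs(xd), t0)
}

# per-signal candidates for the in vitro detector; the input (membrane
# potential or gamma envelope) is low-passed below the gamma band before
# thresholding, then the same moving-median baseline and in vivo sigma
# multipliers apply
invitro_candidates <- function(sig, cfg) {
  xd <- if (isTRUE(cfg$invitro_lowpass_hz > 0))
    so_lowpass(sig, cfg$invitro_lowpass_hz) else sig
  t0 <- ts_t0(xd)
  base_end <- min(cfg$invitro_baseline_s, ts_duration(xd))
  sigma <- baseline_stats(xd, c(t0, t0 + base_end))$sd
  m <- as.numeric(moving_median(xd, cfg$median_window_s))
  list(cand = candidate_pipeline(xd, m, sigma, cfg),
       xd = xd, m = m)
}

#' Detect upstates in vitro by coincidence of two signals
#'
#' Runs the candidate machinery (thresholds `a`/`b`, deletion, merging,
#' splitting) independently on two signals -- typically the membrane
#' potentials of two simultaneously recorded cells, or one membrane potential
#' and the 50-250 Hz envelope of the same cell -- and confirms a candidate
#' from the primary signal iff it overlaps a candidate from the secondary.
#' Each signal is low-passed below the gamma band (default 10 Hz) before
#' thresholding, so crossings track the slow depolarization rather than
#' fast synaptic fluctuations; the dynamic baseline is the same 60 s moving
#' median as in vivo.
#'
#' @param primary,secondary `so_ts` objects on the same timebase.
#' @param cfg A [detection_config()]; baseline sigma is taken from the first
#'   `invitro_baseline_s` seconds of each trace.
#' @return `so_upstates` data frame (metrics from the primary signal).
#' @export
detect_upstates_invitro <- function(primary, secondary,
                                    cfg = detection_config()) {
  stopifnot(inherits(primary, "so_ts"), inherits(secondary, "so_ts"))
  if (abs(ts_fs(primary) - ts_fs(secondary)) > 1e-9 ||
      abs(ts_t0(primary) - ts_t0(secondary)) > 1e-9 ||
      length(primary) != length(secondary))
    stop("primary and secondary signals must share a timebase")
  p <- invitro_candidates(primary, cfg)
  s <- invitro_candidates(secondary, cfg)
  cp <- p$cand
  cs <- s$cand
  if (nrow(cp) == 0) return(empty_events())
  keep <- vapply(seq_len(nrow(cp)), function(i) {
    any(cs$start_s < cp$end_s[i] & cs$end_s > cp$start_s[i])
  }, logical(1))
  cp <- cp[keep, , drop = FALSE]
  if (nrow(cp) == 0) return(empty_events())
  make_events(cp, as.numeric(p$xd), p$m, ts_fs(p$xd), ts_t0(p$xd))
}

#' Summarize upstates over an epoch
#'
#' @param events `so_upstates` data frame.
#' @param epoch `c(start_s, end_s)`; events *starting* in the epoch count.
#' @return List with `incidence_per_min`, `mean_duration_s`, `mean_area`,
#'   and `n`. Duration and area are `NA` when no event falls in the epoch.
#' @export
upstate_metrics <- function(events, epoch) {
  stopifnot(length(epoch) == 2)
  if (epoch[2] <= epoch[1]) stop("zero-length epoch")
  sel <- events$start_s >= epoch[1] & events$start_s < epoch[2]
  n <- sum(sel)
  mins <- (epoch[2] - epoch[1]) / 60
  list(incidence_per_min = n / mins,
       mean_duration_s = if (n) mean(events$duration_s[sel]) else NA_real_,
       mean_area = if (n) mean(events$area[sel]) else NA_real_,
       n = n)
}

#' Match detected intervals against a reference list
#'
#' Greedy one-to-one matching: a detected interval matches a reference
#' interval when both boundary discrepancies are within `tol_s`. Used to
#' score detector output against planted ground truth.
#'
#' @param detected,truth Data frames with `start_s`, `end_s`.
#' @param tol_s Boundary tolerance in seconds (default 0.1).
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
match_intervals <- function(detected, truth, tol_s = 0.1) {
  nd <- nrow(detected)
  nt <- nrow(truth)
  used <- logical(nd)
  tp <- 0L
  for (i in seq_len(nt)) {
    ok <- which(!used &
                  abs(detected$start_s - truth$start_s[i]) <= tol_s &
                  abs(detected$end_s - truth$end_s[i]) <= tol_s)
    if (length(ok)) {
      d <- abs(detected$start_s[ok] - truth$start_s[i]) +
        abs(detected$end_s[ok] - truth$end_s[i])
      used[ok[which.min(d)]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nd - tp
  fn <- nt - tp
  prec <- if (nd) tp / nd else NA_real_
  rec <- if (nt) tp / nt else NA_real_
  f1 <- if (tp) 2 * tp / (2 * tp + fp + fn) else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
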