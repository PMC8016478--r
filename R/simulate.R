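#' Simulation parameters for synthetic slow-oscillation recordings
#'
#' Defines the statistical structure of the emulated recordings: bistable
#' up/down dynamics with sub-1 Hz transitions (gamma-distributed dwell
#' times, up 0.5 s / down 1.0 s by default, giving roughly 40 upstates/min),
#' 1/f background LFP with upstate-locked delta-band deflections and
#' upstate-gated gamma, upstate-locked population spiking, a bimodal
#' trough-to-peak waveform mixture, an optional drug epoch that suppresses
#' upstate incidence and most units' firing while elevating an "activated"
#' subset, inhibitory spike-train couplings implemented by thinning, and a
#' three-cluster intrinsic-feature space.
#'
#' @param duration_s Recording length (default 600).
#' @param lfp_rate_hz LFP sampling rate (default 500).
#' @param wideband_rate_hz Waveform sampling rate (default 20000).
#' @param n_channels LFP channel count (default 4).
#' @param channel_gains Per-channel deflection gains; the strongest channel
#'   is the intended detection channel. `NULL` recycles the default pattern
#'   to `n_channels`.
#' @param up_mean_s,down_mean_s Mean up/down dwell times (s).
#' @param dwell_shape Gamma shape (> 1) of dwell-time distributions.
#' @param min_dwell_s Minimum dwell time (rejection-sampled).
#' @param up_amp_sigma Upstate delta-deflection amplitude in units of the
#'   background broadband SD (default 4).
#' @param noise_exponent Spectral exponent alpha of the 1/f^alpha background.
#' @param edge_smooth_s Gaussian smoothing of upstate edges (s).
#' @param gamma_band_hz,gamma_amp_sigma Upstate-gated gamma band and
#'   amplitude (background-SD units).
#' @param n_units Number of extracellular units.
#' @param class_mix Named probabilities for `Exc`, `Int`, `activated`.
#' @param base_rate_hz Named baseline rates (spikes/s) per class.
#' @param up_gain Multiplicative rate gain inside upstates.
#' @param drug_onset_s Drug time (NULL for no drug epoch).
#' @param drug_incidence_mult Post-drug upstate retention probability.
#' @param drug_rate_mult Post-drug rate multiplier for non-activated units
#'   (<= 1).
#' @param drug_activated_mult Post-drug rate multiplier for activated units
#'   (> 1).
#' @param tp_params List of per-class trough-to-peak latency distributions
#'   (mean, sd, lo, hi in ms); excitatory latencies are planted above
#'   0.55 ms, inhibitory below, activated intermediate.
#' @param conn_params Cross-correlogram coupling parameters: `n_connected`,
#'   `n_independent`, `delay_ms`, `window_ms`, `suppression`, `rate_hz`,
#'   `duration_s`.
#' @param celltype_n,celltype_mix,celltype_profile Cohort size, class mixture
#'   and per-class feature means/SDs for the intrinsic-feature generator
#'   (defaults follow the qualitative profiles: Exc wide spikes / low AHP /
#'   low rheobase; FS low R_in / high rheobase / low sag; LTS high R_in /
#'   high sag / high AHP).
#' @param ic_rate_hz,ic_amp_mv,ic_noise_mv,ic_gamma_amp,ic_rp_mv
#'   Intracellular-pair parameters: sampling rate, upstate depolarization
#'   (mV), white-noise SD (mV), upstate-gated gamma amplitude (mV), resting
#'   potentials (length-2).
#' @param seed Integer seed; together with the parameters it fully
#'   determines every generated output.
#' @return List of class `so_sim_params`.
#' @export
sim_params <- function(duration_s = 600, lfp_rate_hz = 500,
                       wideband_rate_hz = 20000, n_channels = 4,
                       channel_gains = NULL,
                       up_mean_s = 0.45, down_mean_s = 3.5,
                       dwell_shape = c(up = 16, down = 4),
                       min_dwell_s = c(up = 0.3, down = 0.5),
                       up_amp_sigma = 5, noise_exponent = 1,
                       edge_smooth_s = 0.05,
                       gamma_band_hz = c(50, 200), gamma_amp_sigma = 0.5,
                       n_units = 40,
                       class_mix = c(Exc = 0.7, Int = 0.2, activated = 0.1),
                       base_rate_hz = c(Exc = 3, Int = 8, activated = 3),
                       up_gain = 5,
                       drug_onset_s = NULL, drug_incidence_mult = 0.3,
                       drug_rate_mult = 0.2, drug_activated_mult = 3,
                       tp_params = list(
                         Exc = c(mean = 0.75, sd = 0.08, lo = 0.60, hi = 1.20),
                         Int = c(mean = 0.35, sd = 0.06, lo = 0.20, hi = 0.50),
                         activated = c(mean = 0.55, sd = 0.10, lo = 0.40,
                                       hi = 0.75)),
                       conn_params = list(n_connected = 10, n_independent = 20,
                                          delay_ms = 5, window_ms = 4,
                                          suppression = 0.8, rate_hz = 10,
                                          duration_s = 1200),
                       celltype_n = 48,
                       celltype_mix = c(Exc = 0.5, FS = 0.25, LTS = 0.25),
                       celltype_profile = default_celltype_profile(),
                       ic_rate_hz = 2000, ic_amp_mv = 10, ic_noise_mv = 1,
                       ic_gamma_amp = 1.5, ic_rp_mv = c(-70, -68),
                       seed = 1) {
  p <- as.list(environment())
  if (is.null(p$channel_gains))
    p$channel_gains <- rep(c(0.6, 1.0, 0.8, 0.7), length.out = n_channels)
  validate_sim_params(p)
  class(p) <- "so_sim_params"
  p
}

#' Default per-class intrinsic-feature distributions
#'
#' Means and SDs of the six intrinsic features per cell class, respecting
#' the qualitative ordering of the three electrophysiological phenotypes.
#' Units: `r_in` MOhm, `delta_ahp` mV, `sag` unitless, `rheobase` pA,
#' `spike_width` ms, `rp` mV.
#'
#' @return List with `mean` and `sd`, each a 3 x 6 matrix (classes x
#'   features).
#' @export
default_celltype_profile <- function() {
  feats <- CELLTYPE_FEATURES
  cls <- c("Exc", "FS", "LTS")
  mean <- matrix(c(
    # r_in delta_ahp  sag rheobase spike_width   rp
      150,       5, 0.05,      90,       1.10, -72,   # Exc
       80,      14, 0.03,     260,       0.35, -68,   # FS
      300,      22, 0.18,      70,       0.50, -60),  # LTS
    nrow = 3, byrow = TRUE, dimnames = list(cls, feats))
  sd <- matrix(c(
       30,       2, 0.02,      25,       0.15,   3,
       15,       3, 0.015,     50,       0.05,   3,
       50,       3, 0.04,      20,       0.08,   3),
    nrow = 3, byrow = TRUE, dimnames = list(cls, feats))
  list(mean = mean, sd = sd)
}

validate_sim_params <- function(p) {
  if (any(unlist(p$base_rate_hz) < 0)) stop("rates must be >= 0")
  if (abs(sum(p$class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (p$drug_incidence_mult < 0 || p$drug_rate_mult < 0 ||
      p$drug_activated_mult < 0)
    stop("drug multipliers must be >= 0")
  if (any(p$dwell_shape <= 1)) stop("dwell_shape must be > 1")
  if (p$up_amp_sigma < 0 || p$gamma_amp_sigma < 0)
    stop("amplitudes must be >= 0")
  cp <- p$conn_params
  if (cp$suppression < 0 || cp$suppression > 1)
    stop("conn suppression must lie in [0, 1]")
  if (cp$delay_ms < 0 || cp$delay_ms + cp$window_ms > 50)
    stop("suppression window outside the +/-50 ms correlogram window")
  if (any(p$celltype_profile$sd <= 0)) stop("celltype feature SDs must be > 0")
  if (length(p$channel_gains) != p$n_channels)
    stop("channel_gains length must equal n_channels")
  invisible(p)
}

# class labels as an exact (rounded) composition of the mixture, randomly
# permuted, so planted class fractions are reproduced exactly
class_composition <- function(mix, n) {
  counts <- round(mix * n)
  counts[1] <- n - sum(counts[-1])
  sample(rep(names(mix), counts))
}

# deterministic child seeds below 2^31 so sub-generators are independent
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 16807) %% 2147483563 + 1
}

# gamma dwell with rejection below the minimum: keeps states realistic
# (shape > 1 avoids near-zero dwells; rejection enforces the hard floor)
draw_dwell <- function(n, mean_s, shape, min_s) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    out[need] <- stats::rgamma(length(need), shape = shape,
                               scale = mean_s / shape)
    need <- need[out[need] < min_s]
  }
  out
}

# alternating down/up state sequence; upstates after drug onset thinned
generate_state_sequence <- function(p) {
  t_end <- p$duration_s
  starts <- numeric(0)
  ends <- numeric(0)
  t <- 0
  shp <- if (length(p$dwell_shape) == 1)
    c(up = p$dwell_shape, down = p$dwell_shape) else p$dwell_shape
  while (t < t_end) {
    d <- draw_dwell(1, p$down_mean_s, shp[["down"]], p$min_dwell_s[["down"]])
    u <- draw_dwell(1, p$up_mean_s, shp[["up"]], p$min_dwell_s[["up"]])
    s <- t + d
    e <- s + u
    if (s >= t_end) break
    e <- min(e, t_end)
    if (e - s >= p$min_dwell_s[["up"]]) {
      starts <- c(starts, s)
      ends <- c(ends, e)
    }
    t <- s + u
  }
  iv <- data.frame(start_s = starts, end_s = ends)
  if (!is.null(p$drug_onset_s)) {
    post <- iv$start_s >= p$drug_onset_s
    keep <- !post | (stats::runif(nrow(iv)) < p$drug_incidence_mult)
    iv <- iv[keep, , drop = FALSE]
    rownames(iv) <- NULL
  }
  iv
}

# 1/f^alpha Gaussian noise, unit SD, via spectral shaping
one_over_f_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  f <- stats::fft(w)
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k)
  freq[1] <- 1
  shape <- freq^(-alpha / 2)
  shape[1] <- 0  # remove DC
  x <- Re(stats::fft(f * shape, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Delta-band upstate deflection: each upstate contributes the zero-phase
# delta-band response of its own boxcar, normalized to unit peak, so every
# deflection peaks at the configured amplitude and the detection filter
# leaves the waveform essentially unchanged.  Built from the filter's step
# response s(t): pulse(t) = s(t - start) - s(t - end).
delta_band_deflection <- function(intervals, n, fs, band_hz,
                                  support_s = 8) {
  out <- numeric(n)
  if (nrow(intervals) == 0) return(out)
  ns <- round(support_s * fs)
  bf <- signal::butter(3, band_hz / (fs / 2), type = "pass")
  step <- c(numeric(3 * ns), rep(1, 3 * ns))
  sresp <- as.numeric(signal::filtfilt(bf, step))
  onset <- 3 * ns + 1  # index of the step edge within sresp
  for (i in seq_len(nrow(intervals))) {
    a <- round(intervals$start_s[i] * fs) + 1L
    b <- round(intervals$end_s[i] * fs)
    lo <- max(1L, a - ns)
    hi <- min(n, b + ns)
    rel <- (lo:hi)
    grab <- function(edge) {
      idx <- onset + (rel - edge)
      v <- numeric(length(rel))
      ok <- idx >= 1 & idx <= length(sresp)
      v[ok] <- sresp[idx[ok]]
      v[idx > length(sresp)] <- sresp[length(sresp)]
      v
    }
    pulse <- grab(a) - grab(b)
    pk <- max(pulse)
    if (pk > 0) out[rel] <- out[rel] + pulse / pk
  }
  out
}

# smoothed 0/1 upstate indicator on the LFP sample grid
upstate_indicator <- function(intervals, n, fs, smooth_s) {
  ind <- numeric(n)
  for (i in seq_len(nrow(intervals))) {
    a <- max(1L, floor(intervals$start_s[i] * fs) + 1L)
    b <- min(n, ceiling(intervals$end_s[i] * fs))
    if (b >= a) ind[a:b] <- 1
  }
  if (smooth_s > 0) {
    hw <- max(1L, round(3 * smooth_s * fs))
    kx <- (-hw):hw
    kern <- exp(-kx^2 / (2 * (smooth_s * fs)^2))
    kern <- kern / sum(kern)
    ind <- as.numeric(stats::filter(ind, kern, sides = 2))
    ind[is.na(ind)] <- 0
  }
  ind
}

# rate multiplier at time t for a unit of a given class
segment_rate <- function(class, in_up, post_drug, p) {
  r <- p$base_rate_hz[[class]]
  if (in_up) r <- r * p$up_gain
  if (post_drug) {
    r <- r * if (class == "activated") p$drug_activated_mult else
      p$drug_rate_mult
  }
  r
}

# inhomogeneous Poisson train with piecewise-constant rate defined by the
# upstate intervals and (optionally) the drug onset
draw_unit_train <- function(class, intervals, p) {
  cuts <- sort(unique(c(0, p$duration_s, intervals$start_s, intervals$end_s,
                        if (!is.null(p$drug_onset_s)) p$drug_onset_s)))
  cuts <- cuts[cuts >= 0 & cuts <= p$duration_s]
  spikes <- numeric(0)
  for (i in seq_len(length(cuts) - 1)) {
    s <- cuts[i]
    e <- cuts[i + 1]
    if (e <= s) next
    mid <- (s + e) / 2
    in_up <- any(intervals$start_s <= mid & intervals$end_s > mid)
    post <- !is.null(p$drug_onset_s) && mid >= p$drug_onset_s
    r <- segment_rate(class, in_up, post, p)
    n <- stats::rpois(1, r * (e - s))
    if (n) spikes <- c(spikes, stats::runif(n, s, e))
  }
  sort(spikes)
}

#' Generate a synthetic slow-oscillation recording with ground truth
#'
#' Produces a multichannel LFP (1/f background plus upstate-locked
#' delta-band deflections and upstate-gated gamma), sorted spike trains
#' whose rates are elevated inside every ground-truth upstate (and modulated
#' by the drug epoch when configured), per-unit mean waveforms with planted
#' trough-to-peak latencies, and per-spike amplitudes.
#'
#' @param params A [sim_params()] object.
#' @return List with `lfp` (samples x channels matrix), `lfp_fs`, `trains`
#'   (named list of spike-time vectors), `units` (data frame: `unit_id`,
#'   `class`, `planted_tp_ms`), `waveforms` (named list, attribute `fs`),
#'   `amplitudes` (named list), and `truth` (list: `upstate_intervals`,
#'   `unit_classes`, `drug_onset_s`).
#' @export
generate_so_recording <- function(params = sim_params()) {
  p <- validate_sim_params(params)
  if (p$duration_s < p$up_mean_s + p$down_mean_s)
    stop("duration too short to contain one full dwell cycle")
  n <- round(p$duration_s * p$lfp_rate_hz)

  set.seed(child_seed(p$seed, 1))
  intervals <- generate_state_sequence(p)

  set.seed(child_seed(p$seed, 2))
  defl <- delta_band_deflection(intervals, n, p$lfp_rate_hz,
                                c(0.5, 4))
  ind <- upstate_indicator(intervals, n, p$lfp_rate_hz, p$edge_smooth_s)
  gamma_carrier <- if (p$gamma_amp_sigma > 0) {
    bf <- signal::butter(3, p$gamma_band_hz / (p$lfp_rate_hz / 2),
                         type = "pass")
    g <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
    g / stats::sd(g)
  } else numeric(n)
  lfp <- matrix(0, n, p$n_channels)
  for (ch in seq_len(p$n_channels)) {
    lfp[, ch] <- one_over_f_noise(n, p$noise_exponent) +
      p$channel_gains[ch] * (p$up_amp_sigma * defl +
                               p$gamma_amp_sigma * gamma_carrier * ind)
  }

  set.seed(child_seed(p$seed, 3))
  classes <- class_composition(p$class_mix, p$n_units)
  ids <- sprintf("u%02d", seq_len(p$n_units))
  trains <- stats::setNames(lapply(classes, draw_unit_train,
                                   intervals = intervals, p = p), ids)

  wf <- generate_unit_waveforms(p, classes = classes,
                                seed = child_seed(p$seed, 4))
  set.seed(child_seed(p$seed, 5))
  amplitudes <- stats::setNames(lapply(seq_len(p$n_units), function(i) {
    mu <- stats::runif(1, 60, 150)
    stats::rnorm(length(trains[[i]]), mu, 0.1 * mu)
  }), ids)

  units <- data.frame(unit_id = ids, class = classes,
                      planted_tp_ms = wf$info$tp_ms,
                      stringsAsFactors = FALSE)
  list(lfp = lfp, lfp_fs = p$lfp_rate_hz, trains = trains, units = units,
       waveforms = wf$waveforms, amplitudes = amplitudes,
       truth = list(upstate_intervals = intervals, unit_classes = units,
                    drug_onset_s = p$drug_onset_s))
}

#' Generate mean spike waveforms with planted trough-to-peak latencies
#'
#' Each waveform is a negative-trough biphasic template (raised-cosine
#' lobes) whose trough and subsequent peak fall exactly on wideband samples,
#' so the measured trough-to-peak latency matches the planted value to
#' within one sample period. Excitatory units are planted above the 0.55 ms
#' boundary, inhibitory units below, "activated" units at intermediate
#' latencies.
#'
#' @param params A [sim_params()].
#' @param classes Optional character vector of unit classes; defaults to a
#'   draw from `params$class_mix` of length `params$n_units`.
#' @param seed Seed (defaults to a child of `params$seed`).
#' @return List with `waveforms` (named list of numeric vectors, attribute
#'   `fs`) and `info` (data frame `unit_id`, `class`, `tp_ms`).
#' @export
generate_unit_waveforms <- function(params = sim_params(), classes = NULL,
                                    seed = NULL) {
  p <- params
  if (abs(sum(p$class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  set.seed(if (is.null(seed)) child_seed(p$seed, 4) else seed)
  if (is.null(classes))
    classes <- class_composition(p$class_mix, p$n_units)
  fs <- p$wideband_rate_hz
  dt_ms <- 1000 / fs
  tps <- vapply(classes, function(cl) {
    q <- p$tp_params[[cl]]
    x <- stats::rnorm(1, q[["mean"]], q[["sd"]])
    while (x < q[["lo"]] || x > q[["hi"]])
      x <- stats::rnorm(1, q[["mean"]], q[["sd"]])
    round(x / dt_ms) * dt_ms  # quantize the planted latency to the grid
  }, numeric(1))
  rep_w <- c(Exc = 0.5, Int = 0.3, activated = 0.4)
  ids <- sprintf("u%02d", seq_along(classes))
  wfs <- stats::setNames(lapply(seq_along(classes), function(i) {
    biphasic_template(tps[i], fs, w_peak_ms = rep_w[[classes[i]]])
  }), ids)
  attr(wfs, "fs") <- fs
  list(waveforms = wfs,
       info = data.frame(unit_id = ids, class = classes, tp_ms = unname(tps),
                         stringsAsFactors = FALSE))
}

# raised-cosine biphasic template: trough at 1 ms, peak tp_ms later
biphasic_template <- function(tp_ms, fs, trough_amp = -100, peak_frac = 0.4,
                              w_trough_ms = 0.1, w_peak_ms = 0.4,
                              span_ms = 4) {
  t <- seq(0, span_ms, by = 1000 / fs)
  t_tr <- 1
  t_pk <- t_tr + tp_ms
  lobe <- function(center, width) {
    u <- (t - center) / width
    ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)
  }
  trough_amp * lobe(t_tr, w_trough_ms) -
    trough_amp * peak_frac * lobe(t_pk, w_peak_ms)
}

#' Generate spike-train pairs with planted inhibitory couplings
#'
#' Connected pairs are built by thinning: each post-synaptic spike falling
#' in the `(delay, delay + window)` lag window after any pre-synaptic spike
#' is deleted with probability `suppression`, so planted suppression maps
#' directly onto a cross-correlogram trough. Independent pairs are
#' uncoupled Poisson trains.
#'
#' @param params A [sim_params()]; coupling settings come from
#'   `params$conn_params`.
#' @return List with `trains` (named list), `truth` (data frame of planted
#'   connections: `pre_id`, `post_id`, `delay_ms`, `suppression`),
#'   `independent_pairs` (data frame `pre_id`, `post_id`), and `duration_s`.
#' @export
generate_connected_trains <- function(params = sim_params()) {
  p <- validate_sim_params(params)
  cp <- p$conn_params
  if (cp$n_connected + cp$n_independent < 1) stop("need at least one pair")
  set.seed(child_seed(p$seed, 6))
  dur <- cp$duration_s
  delay_s <- cp$delay_ms / 1000
  win_s <- cp$window_ms / 1000
  hom_train <- function() sort(stats::runif(stats::rpois(1, cp$rate_hz * dur),
                                            0, dur))
  trains <- list()
  conns <- list()
  for (k in seq_len(cp$n_connected)) {
    pre <- hom_train()
    post <- hom_train()
    if (length(pre)) {
      in_win <- (findInterval(post - delay_s, pre) -
                   findInterval(post - delay_s - win_s, pre)) > 0
      drop <- in_win & (stats::runif(length(post)) < cp$suppression)
      post <- post[!drop]
    }
    pid <- sprintf("c%02d_pre", k)
    qid <- sprintf("c%02d_post", k)
    trains[[pid]] <- pre
    trains[[qid]] <- post
    conns[[k]] <- data.frame(pre_id = pid, post_id = qid,
                             delay_ms = cp$delay_ms,
                             suppression = cp$suppression,
                             stringsAsFactors = FALSE)
  }
  ind <- list()
  for (k in seq_len(cp$n_independent)) {
    aid <- sprintf("i%02d_a", k)
    bid <- sprintf("i%02d_b", k)
    trains[[aid]] <- hom_train()
    trains[[bid]] <- hom_train()
    ind[[k]] <- data.frame(pre_id = aid, post_id = bid,
                           stringsAsFactors = FALSE)
  }
  list(trains = trains,
       truth = if (length(conns)) do.call(rbind, conns) else
         data.frame(pre_id = character(0), post_id = character(0),
                    delay_ms = numeric(0), suppression = numeric(0)),
       independent_pairs = if (length(ind)) do.call(rbind, ind) else
         data.frame(pre_id = character(0), post_id = character(0)),
       duration_s = dur)
}

#' Generate an intrinsic-feature table with planted class labels
#'
#' Draws one row per cell from per-class multivariate normals with diagonal
#' covariance, following the configured class profiles.
#'
#' @param params A [sim_params()]; uses `celltype_n`, `celltype_mix`,
#'   `celltype_profile`, and `seed`.
#' @return List with `features` (data frame: `cell_id` plus the six feature
#'   columns) and `labels` (character vector).
#' @export
generate_feature_table <- function(params = sim_params()) {
  p <- validate_sim_params(params)
  prof <- p$celltype_profile
  set.seed(child_seed(p$seed, 7))
  counts <- round(p$celltype_mix * p$celltype_n)
  counts[1] <- p$celltype_n - sum(counts[-1])
  labels <- rep(names(counts), counts)
  rows <- lapply(labels, function(cl) {
    mu <- prof$mean[cl, ]
    sd <- prof$sd[cl, ]
    stats::setNames(stats::rnorm(length(mu), mu, sd), names(mu))
  })
  feats <- as.data.frame(do.call(rbind, rows))
  feats <- cbind(cell_id = sprintf("cell%02d", seq_along(labels)), feats,
                 stringsAsFactors = FALSE)
  list(features = feats, labels = labels)
}

#' Generate a cohort with one planted boundary cell
#'
#' Draws the standard intrinsic-feature cohort, fits the typing model to it
#' (the reference model), and plants one additional synthetic cell at the
#' reference model's decision boundary between the two closest mixture
#' components: the point where their posterior probabilities are equal,
#' found by bisection along the segment joining the component means in PCA
#' space and mapped back to feature space. Assigning the full cohort under
#' the reference model leaves exactly this cell below the 90% posterior
#' cutoff (its maximum posterior is 0.5 by construction).
#'
#' @param params A [sim_params()].
#' @return List with `features` (n + 1 rows), `labels` (planted labels, the
#'   boundary cell labelled `"boundary"`), `boundary_index`, and
#'   `reference_model` (the model fitted to the reference cohort).
#' @export
generate_boundary_cohort <- function(params = sim_params()) {
  ft <- generate_feature_table(params)
  model <- fit_celltype_model(ft$features)
  mu <- model$parameters$mean  # 2 x 3, PCA space
  d <- as.matrix(stats::dist(t(mu)))
  d[d == 0] <- Inf
  pair <- which(d == min(d), arr.ind = TRUE)[1, ]
  la <- model$label_map[pair[1]]
  lb <- model$label_map[pair[2]]
  score_to_row <- function(s) {
    z <- as.numeric(model$loadings %*% s)
    stats::setNames(as.list(z * model$scale + model$center),
                    rownames(model$loadings))
  }
  post_diff <- function(t) {
    s <- (1 - t) * mu[, pair[1]] + t * mu[, pair[2]]
    asg <- assign_celltype(model, as.data.frame(score_to_row(s)))
    asg[[paste0("p_", la)]] - asg[[paste0("p_", lb)]]
  }
  lo <- 0
  hi <- 1
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (post_diff(mid) > 0) lo <- mid else hi <- mid
  }
  s <- (1 - (lo + hi) / 2) * mu[, pair[1]] + (lo + hi) / 2 * mu[, pair[2]]
  row <- as.data.frame(score_to_row(s))
  feats <- rbind(ft$features[, -1], row)
  feats <- cbind(cell_id = sprintf("cell%02d", seq_len(nrow(feats))), feats,
                 stringsAsFactors = FALSE)
  list(features = feats, labels = c(ft$labels, "boundary"),
       boundary_index = nrow(feats), reference_model = model)
}

#' Generate a pair of intracellular traces locked to shared upstates
#'
#' Both membrane-potential traces depolarize by `ic_amp_mv` inside every
#' ground-truth upstate, with independent white noise and upstate-gated
#' 50-250 Hz activity, emulating simultaneously recorded cells.
#'
#' @param truth List with an `upstate_intervals` data frame (e.g. from
#'   [generate_so_recording()], or built directly).
#' @param params A [sim_params()].
#' @return List of two `so_ts` traces (`cell1`, `cell2`) plus
#'   `upstate_intervals`.
#' @export
generate_intracellular_pair <- function(truth, params = sim_params()) {
  p <- validate_sim_params(params)
  iv <- truth$upstate_intervals
  if (is.null(iv) || nrow(iv) < 1) stop("truth must contain >= 1 interval")
  fs <- p$ic_rate_hz
  n <- round(p$duration_s * fs)
  set.seed(child_seed(p$seed, 8))
  ind <- upstate_indicator(iv, n, fs, smooth_s = 0.02)
  make_cell <- function(rp) {
    v <- rp + p$ic_amp_mv * ind
    if (p$ic_noise_mv > 0) v <- v + stats::rnorm(n, 0, p$ic_noise_mv)
    if (p$ic_gamma_amp > 0) {
      bf <- signal::butter(3, c(50, 250) / (fs / 2), type = "pass")
      g <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
      v <- v + p$ic_gamma_amp * (g / stats::sd(g)) * ind
    }
    so_ts(v, fs)
  }
  list(cell1 = make_cell(p$ic_rp_mv[1]), cell2 = make_cell(p$ic_rp_mv[2]),
       upstate_intervals = iv)
}

#' Simulate current-step voltage responses of a cell with known features
#'
#' Builds analytic voltage traces (RC-style rise, sag relaxation,
#' raised-cosine spikes with a bounded after-hyperpolarization) from planted
#' intrinsic features, so [extract_features()] can be validated against
#' ground truth.
#'
#' @param cell List of planted features: `rp` (mV), `r_in` (MOhm), `sag`
#'   (ratio), `rheobase` (pA), `spike_width` (ms), `delta_ahp` (mV).
#' @param currents Step currents in pA (default -150 and 50..300 by 25).
#' @param fs Sampling rate (default 20000).
#' @param pre_s,step_s,post_s Trace segment durations.
#' @param tau_s Membrane time constant (default 0.02).
#' @param tau_sag_s Sag relaxation time constant (default 0.08).
#' @return List of steps in the format accepted by [extract_features()].
#' @export
simulate_current_steps <- function(cell,
                                   currents = c(-150, seq(50, 300, by = 25)),
                                   fs = 20000, pre_s = 0.2, step_s = 0.5,
                                   post_s = 0.3, tau_s = 0.02,
                                   tau_sag_s = 0.08) {
  n <- round((pre_s + step_s + post_s) * fs)
  tm <- (seq_len(n) - 1) / fs
  on <- pre_s
  off <- pre_s + step_s
  lapply(currents, function(I) {
    v <- rep(cell$rp, n)
    defl_ss <- I / 1000 * cell$r_in  # pA -> nA, times MOhm = mV
    in_step <- tm >= on & tm < off
    ts_rel <- tm[in_step] - on
    if (I < 0 && cell$sag > 0) {
      pk <- defl_ss / (1 - cell$sag)
      t_pk <- 7 * tau_s
      rise <- pk * (1 - exp(-ts_rel / tau_s))
      relax <- defl_ss + (pk * (1 - exp(-t_pk / tau_s)) - defl_ss) *
        exp(-(ts_rel - t_pk) / tau_sag_s)
      v[in_step] <- cell$rp + ifelse(ts_rel <= t_pk, rise, relax)
    } else {
      v[in_step] <- cell$rp + defl_ss * (1 - exp(-ts_rel / tau_s))
    }
    # post-step relaxation back to rest
    post_sel <- tm >= off
    v[post_sel] <- cell$rp + (v[max(which(in_step))] - cell$rp) *
      exp(-(tm[post_sel] - off) / tau_s)
    if (I > 0 && I >= cell$rheobase - 1e-9) {
      # single stereotyped spike 100 ms into the step
      t_sp <- on + 0.1
      base <- cell$rp + defl_ss
      w_s <- cell$spike_width / 1000
      u <- (tm - t_sp) / w_s
      spike <- ifelse(abs(u) < 1, (30 - base) * cos(pi * u / 2)^2, 0)
      t_ahp <- t_sp + w_s + 0.004
      ua <- (tm - t_ahp) / 0.004
      ahp <- ifelse(abs(ua) < 1, -cell$delta_ahp * cos(pi * ua / 2)^2, 0)
      v <- v + spike + ahp
    }
    list(current_pA = I, vm = so_ts(v, fs), step_window_s = c(on, off))
  })
}
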