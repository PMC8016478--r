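# Brute-force reference for the staged in vivo detector: enumerates every
# sample against the thresholds and applies the deletion / merging /
# splitting / confirmation rules literally with plain loops.  Shares only
# the preprocessing (delta filter, baseline sigma, moving median) with the
# implementation under test.
brute_force_detect <- function(lfp, pop, cfg) {
  xd <- so_bandpass(lfp, cfg$delta_band_hz[1], cfg$delta_band_hz[2])
  fs <- ts_fs(xd)
  t0 <- ts_t0(xd)
  x <- as.numeric(xd)
  n <- length(x)
  sigma <- baseline_stats(xd, c(t0, t0 + cfg$baseline_duration_s))$sd
  m <- as.numeric(moving_median(xd, cfg$median_window_s))
  a <- m + cfg$k_a * sigma
  b <- m + cfg$k_b * sigma
  eps <- 1e-9

  # candidates: scan every sample
  cands <- list()
  cur <- NULL
  for (i in seq_len(n)) {
    if (x[i] > a[i]) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
    } else if (!is.null(cur)) {
      cands[[length(cands) + 1]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) cands[[length(cands) + 1]] <- cur

  dur_of <- function(c) (c[2] - c[1] + 1) / fs
  # delete shorter than the minimum
  cands <- Filter(function(c) dur_of(c) >= cfg$min_duration_s - eps, cands)

  # merge gaps smaller than merge_gap_s, left to right
  merged <- list()
  for (c in cands) {
    k <- length(merged)
    if (k > 0 && (c[1] - 1 - merged[[k]][2]) / fs < cfg$merge_gap_s - eps) {
      merged[[k]][2] <- max(merged[[k]][2], c[2])
    } else {
      merged[[length(merged) + 1]] <- c
    }
  }

  # split at dips below b (down-crossing then up-crossing strictly inside)
  split <- list()
  for (c in merged) {
    frag_start <- c[1]
    i <- c[1]
    while (i <= c[2]) {
      if (x[i] < b[i] && i > c[1]) {
        j <- i
        while (j <= c[2] && x[j] < b[j]) j <- j + 1
        if (j <= c[2]) {  # re-crossed above b inside the candidate
          midpoint <- (i + j) / 2  # down-crossing at i, up-crossing at j
          left_end <- floor(midpoint - eps)
          split[[length(split) + 1]] <- c(frag_start, left_end)
          frag_start <- left_end + 1
        }
        i <- j
      } else {
        i <- i + 1
      }
    }
    split[[length(split) + 1]] <- c(frag_start, c[2])
  }
  split <- Filter(function(c) dur_of(c) >= cfg$min_duration_s - eps, split)

  # population confirmation
  win <- attr(pop, "window_s")
  base <- baseline_stats(pop, c(t0, t0 + cfg$baseline_duration_s))
  thr <- base$mean + cfg$pop_threshold_sigma * base$sd
  confirmed <- list()
  for (c in split) {
    cs <- t0 + (c[1] - 1) / fs
    ce <- t0 + c[2] / fs
    hit <- FALSE
    for (w in seq_len(nrow(pop))) {
      if (pop$t[w] < ce && pop$t[w] + win > cs && pop$rate[w] > thr) {
        hit <- TRUE
        break
      }
    }
    if (hit) confirmed[[length(confirmed) + 1]] <- c(cs, ce)
  }
  if (!length(confirmed))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  out <- do.call(rbind, confirmed)
  data.frame(start_s = out[, 1], end_s = out[, 2])
}

# random test signal with embedded suprathreshold bumps, plus a population
# trace loosely coupled to the bumps
random_detection_case <- function(seed, n = 20000, fs = 100) {
  set.seed(seed)
  x <- stats::rnorm(n)
  n_bump <- sample(5:25, 1)
  starts <- sort(sample(seq_len(n - 200), n_bump))
  for (s in starts) {
    len <- sample(5:120, 1)
    amp <- stats::runif(1, 1, 8)
    idx <- s:min(n, s + len)
    x[idx] <- x[idx] + amp
  }
  lfp <- so_ts(x, fs)
  dur <- n / fs
  n_win <- ceiling(dur / 0.1)
  rate <- stats::rpois(n_win, 3) + 30 * (stats::runif(n_win) < 0.3)
  pop <- data.frame(t = (seq_len(n_win) - 1) * 0.1, rate = rate)
  attr(pop, "window_s") <- 0.1
  class(pop) <- c("so_poprate", "data.frame")
  cfg <- detection_config(baseline_duration_s = 30, median_window_s = 10)
  list(lfp = lfp, pop = pop, cfg = cfg)
}

# deterministic spike train at a fixed rate over [t0, t1)
regular_train <- function(rate_hz, t0, t1) {
  if (rate_hz <= 0) return(numeric(0))
  seq(t0, t1 - 1e-9, by = 1 / rate_hz)
}
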