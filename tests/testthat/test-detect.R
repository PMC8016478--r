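cand_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(start_s = m[, 1], end_s = m[, 2])
}

test_that("deletion removes strictly sub-minimum candidates only", {
  cands <- cand_df(0, 0.199, 1, 1.2, 2, 2.5)
  out <- delete_short(cands, 0.2)
  expect_equal(out$start_s, c(1, 2))
  expect_equal(nrow(delete_short(cand_df(0, 0.2), 0.2)), 1)
  expect_equal(nrow(delete_short(cands[0, ], 0.2)), 0)
})

test_that("merging joins sub-gap neighbours transitively and is idempotent", {
  expect_equal(merge_close(cand_df(0, 0.25, 0.40, 0.70), 0.3),
               cand_df(0, 0.70))
  expect_equal(merge_close(cand_df(0, 0.25, 0.60, 0.90), 0.3),
               cand_df(0, 0.25, 0.60, 0.90))
  chain <- cand_df(0, 0.3, 0.5, 0.8, 1.0, 1.3)  # gaps of 0.2 s
  expect_equal(merge_close(chain, 0.3), cand_df(0, 1.3))
  set.seed(10)
  for (i in 1:20) {
    s <- sort(runif(10, 0, 10))
    cands <- data.frame(start_s = s, end_s = s + runif(10, 0.01, 0.2))
    cands <- cands[c(TRUE, diff(s) > 0.25), ]  # keep non-overlapping
    once <- merge_close(cands, 0.3)
    expect_equal(merge_close(once, 0.3), once)
  }
})

test_that("splitting at dips below b uses crossing midpoints", {
  fs <- 100
  x <- rep(5, 1000)
  sig <- so_ts(x, fs)
  b <- rep(1, 1000)
  cand <- cand_df(1, 9)
  expect_equal(split_by_b(cand, sig, b), cand)  # never dips below b

  # one symmetric dip below b centered at 5 s -> split meets at the center
  x2 <- x
  x2[480:520] <- 0
  out2 <- split_by_b(cand, so_ts(x2, fs), b)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$end_s[1], out2$start_s[2])
  expect_lt(abs(out2$end_s[1] - 5.0), 1.5 / fs)

  # two dips -> three fragments with hand-computed midpoints:
  # dip A over samples 201..240 -> crossings at 201/241, midpoint 221
  # dip B over samples 701..720 -> crossings at 701/721, midpoint 711
  x3 <- x
  x3[201:240] <- 0
  x3[701:720] <- 0
  out3 <- split_by_b(cand, so_ts(x3, fs), b)
  expect_equal(nrow(out3), 3)
  expect_equal(out3$end_s[1], 2.20)  # floor(221 - eps) = sample 220 -> 2.20 s
  expect_equal(out3$start_s[2], 2.20)
  expect_equal(out3$end_s[2], 7.10)
  expect_equal(out3$start_s[3], 7.10)
})

test_that("population confirmation requires one suprathreshold overlap", {
  pop <- population_rate(list(c(seq(0, 0.999, 0.01), seq(5, 5.099, 0.01))),
                         0.1, 0, 10)
  base <- list(mean = mean(pop$rate), sd = sd(pop$rate))
  cands <- cand_df(0.2, 0.6, 3.0, 3.4, 5.0, 5.3)
  out <- confirm_population(cands, pop, base, 1)
  # candidate at 3.0-3.4 s has zero coincident spiking -> dropped
  expect_equal(out$start_s, c(0.2, 5.0))
  silent <- population_rate(list(numeric(0)), 0.1, 0, 10)
  sbase <- list(mean = 0, sd = 0)
  expect_equal(nrow(confirm_population(cands, silent, sbase, 1)), 0)
})

test_that("a clean suprathreshold deflection with spiking gives one event", {
  fs <- 100
  dur <- 120
  n <- dur * fs
  set.seed(11)
  ev_start <- 60
  ev_end <- 60.5
  pulse <- slowosc:::delta_band_deflection(
    data.frame(start_s = ev_start, end_s = ev_end), n, fs, c(0.5, 4))
  x <- rnorm(n, sd = 0.1) + 5 * pulse
  lfp <- so_ts(x, fs)
  train <- seq(ev_start, ev_end - 1e-3, by = 0.005)  # burst inside the event
  pop <- population_rate(list(train), 0.1, 0, dur)
  cfg <- detection_config(baseline_duration_s = 30, median_window_s = 10)
  ev <- detect_upstates_invivo(lfp, pop, cfg)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$start_s - ev_start), 0.1 + 1e-9)
  expect_lt(abs(ev$end_s - ev_end), 0.1 + 1e-9)
})

test_that("signal below threshold everywhere yields no events", {
  fs <- 100
  set.seed(12)
  lfp <- so_ts(rnorm(12000, sd = 0.01), fs)
  pop <- population_rate(list(seq(0, 119, by = 0.01)), 0.1, 0, 120)
  cfg <- detection_config(baseline_duration_s = 30, median_window_s = 10)
  ev <- detect_upstates_invivo(lfp, pop, cfg)
  expect_equal(nrow(ev), 0)
})

test_that("staged detector equals the brute-force literal-rule reference", {
  for (seed in 1:20) {
    case <- random_detection_case(seed, n = 10000)
    ref <- brute_force_detect(case$lfp, case$pop, case$cfg)
    got <- detect_upstates_invivo(case$lfp, case$pop, case$cfg)
    expect_equal(got$start_s, ref$start_s, tolerance = 1e-12,
                 info = paste("seed", seed))
    expect_equal(got$end_s, ref$end_s, tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("raising k_a never increases the pre-merge candidate count", {
  case <- random_detection_case(42, n = 10000)
  xd <- so_bandpass(case$lfp, 0.5, 4)
  sigma <- baseline_stats(xd, c(0, 30))$sd
  m <- as.numeric(moving_median(xd, 10))
  counts <- sapply(c(1.0, 1.5, 2.0, 2.5, 3.0), function(k) {
    sum(rle(as.numeric(xd) > m + k * sigma)$values)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("detector output is sorted, non-overlapping, confirmed, >= minimum", {
  rec <- generate_so_recording(sim_params(seed = 2))
  lfp <- so_ts(rec$lfp[, 2], rec$lfp_fs)
  pop <- population_rate(rec$trains, 0.1, 0, ts_duration(lfp))
  ev <- detect_upstates_invivo(lfp, pop)
  expect_true(all(diff(ev$start_s) > 0))
  expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
  expect_true(all(ev$duration_s >= 0.2 - 1e-9))
  expect_true(all(ev$confirmed))
  expect_true(all(ev$area >= 0))
})

test_that("detector errors on short recordings and uncovered population", {
  lfp <- so_ts(rnorm(1000), 100)
  pop <- population_rate(list(1:5), 0.1, 0, 10)
  expect_error(detect_upstates_invivo(lfp, pop, detection_config()),
               "baseline")
  cfg <- detection_config(baseline_duration_s = 5, median_window_s = 2)
  pop_short <- population_rate(list(1:3), 0.1, 0, 4)
  expect_error(detect_upstates_invivo(lfp, pop_short, cfg), "cover")
})

test_that("in vitro detection requires coincidence across the two signals", {
  fs <- 200
  dur <- 120
  n <- dur * fs
  set.seed(13)
  mk <- function(events) {
    v <- rnorm(n, -70, 0.3)
    for (e in events) v[(e[1] * fs):(e[2] * fs)] <- v[(e[1] * fs):(e[2] * fs)] + 10
    so_ts(v, fs)
  }
  shared <- list(c(70, 70.5), c(90, 90.6))
  v1 <- mk(c(shared, list(c(100, 100.4))))  # one event unique to cell 1
  v2 <- mk(shared)
  cfg <- detection_config(median_window_s = 30)
  ev <- detect_upstates_invitro(v1, v2, cfg)
  expect_equal(nrow(ev), 2)
  expect_true(all(abs(ev$start_s - c(70, 90)) < 0.1))
  expect_error(detect_upstates_invitro(v1, so_ts(rnorm(10), 100)), "timebase")
})

test_that("upstate metrics compute incidence, duration, and boxcar area", {
  ev <- data.frame(start_s = seq(0, 54, by = 6), end_s = seq(0.5, 54.5, by = 6),
                   duration_s = 0.5, area = 2, peak = 4, confirmed = TRUE)
  m <- upstate_metrics(ev, c(0, 60))
  expect_equal(m$incidence_per_min, 10)
  expect_equal(m$mean_duration_s, 0.5)
  none <- upstate_metrics(ev, c(100, 160))
  expect_equal(none$incidence_per_min, 0)
  expect_true(is.na(none$mean_duration_s))
  expect_error(upstate_metrics(ev, c(5, 5)), "epoch")

  # boxcar of height h above the median over length L -> area = h * L
  fs <- 100
  x <- rep(0, 12000)
  x[6001:6200] <- 3  # h = 3, L = 2 s
  lfp <- so_ts(x, fs)
  sig <- so_ts(x, fs)
  m0 <- rep(0, 12000)
  cand <- data.frame(start_s = 60, end_s = 62)
  meas <- slowosc:::event_measures(cand, x, m0, fs, 0)
  expect_equal(meas$area, 6, tolerance = 1e-9)
  expect_equal(meas$peak, 3)
})
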