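test_that("identical parameters and seed give bit-identical outputs", {
  p <- sim_params(seed = 9, duration_s = 60, n_units = 8,
                  conn_params = list(n_connected = 2, n_independent = 2,
                                     delay_ms = 5, window_ms = 4,
                                     suppression = 0.8, rate_hz = 10,
                                     duration_s = 120))
  a <- generate_so_recording(p)
  b <- generate_so_recording(p)
  expect_identical(a$lfp, b$lfp)
  expect_identical(a$trains, b$trains)
  expect_identical(a$waveforms, b$waveforms)
  expect_identical(generate_connected_trains(p), generate_connected_trains(p))
  expect_identical(generate_feature_table(p), generate_feature_table(p))
})

test_that("simulation rejects invalid parameters", {
  expect_error(generate_so_recording(sim_params(duration_s = 2)),
               "dwell cycle")
  expect_error(sim_params(class_mix = c(Exc = 0.5, Int = 0.2,
                                        activated = 0.1)), "sum to 1")
  expect_error(sim_params(conn_params = list(n_connected = 1,
                                             n_independent = 0, delay_ms = 48,
                                             window_ms = 4, suppression = 0.8,
                                             rate_hz = 10, duration_s = 60)),
               "window")
  p_bad <- sim_params()
  p_bad$celltype_profile$sd[1, 1] <- 0
  expect_error(slowosc:::validate_sim_params(p_bad), "SD")
})

test_that("ground-truth intervals are sorted, disjoint, bounded, long enough", {
  for (s in 1:3) {
    rec <- generate_so_recording(sim_params(seed = s, duration_s = 300))
    iv <- rec$truth$upstate_intervals
    expect_true(all(iv$start_s >= 0 & iv$end_s <= 300))
    expect_true(all(iv$end_s > iv$start_s))
    expect_true(all(diff(iv$start_s) > 0))
    expect_true(all(iv$start_s[-1] >= iv$end_s[-nrow(iv)]))
    expect_true(all(iv$end_s - iv$start_s >= 0.3 - 1e-9))
  }
})

test_that("zeroed effects give a stationary negative control", {
  p <- sim_params(seed = 4, duration_s = 300, up_amp_sigma = 0,
                  gamma_amp_sigma = 0, up_gain = 1, n_units = 20)
  rec <- generate_so_recording(p)
  expect_gt(nrow(rec$truth$upstate_intervals), 0)  # truth still emitted
  # LFP is pure background: no delta-band contrast between states
  lfp <- so_ts(rec$lfp[, 2], rec$lfp_fs)
  xd <- as.numeric(so_bandpass(lfp, 0.5, 4))
  iv <- rec$truth$upstate_intervals
  fs <- rec$lfp_fs
  up_idx <- unlist(lapply(seq_len(nrow(iv)), function(i)
    (round(iv$start_s[i] * fs) + 1):round(iv$end_s[i] * fs)))
  expect_lt(abs(sd(xd[up_idx]) / sd(xd[-up_idx]) - 1), 0.15)
  # spiking is stationary: up-state rate matches down-state rate
  pop <- population_rate(rec$trains, 0.1, 0, 300)
  up <- sapply(pop$t, function(t0) any(iv$start_s <= t0 & iv$end_s > t0 + 0.1))
  expect_lt(abs(mean(pop$rate[up]) / mean(pop$rate[!up]) - 1), 0.1)
})

test_that("zero incidence multiplier removes all post-drug upstates", {
  p <- sim_params(seed = 5, duration_s = 300, drug_onset_s = 150,
                  drug_incidence_mult = 0)
  rec <- generate_so_recording(p)
  iv <- rec$truth$upstate_intervals
  expect_gt(sum(iv$start_s < 150), 0)
  expect_equal(sum(iv$start_s >= 150), 0)
})

test_that("stationary unit spike counts obey the Poisson expectation", {
  p <- sim_params(seed = 6, duration_s = 600, up_gain = 1, n_units = 6,
                  class_mix = c(Exc = 1, Int = 0, activated = 0),
                  base_rate_hz = c(Exc = 5, Int = 8, activated = 3))
  rec <- generate_so_recording(p)
  for (tr in rec$trains) {
    expected <- 5 * 600
    expect_lt(abs(length(tr) - expected), 4 * sqrt(expected))
  }
})

test_that("waveform trough-to-peak latencies match the planted values", {
  p <- sim_params(n_units = 80, seed = 7)
  wf <- generate_unit_waveforms(p)
  fs <- attr(wf$waveforms, "fs")
  tol <- 1000 / fs  # one wideband sample in ms
  for (i in seq_along(wf$waveforms)) {
    f <- waveform_features(wf$waveforms[[i]], fs)
    expect_lt(abs(f$tp_latency_ms - wf$info$tp_ms[i]), tol + 1e-9)
  }
  # class construction respects the 0.55 ms boundary
  expect_true(all(wf$info$tp_ms[wf$info$class == "Exc"] > 0.55))
  expect_true(all(wf$info$tp_ms[wf$info$class == "Int"] < 0.55))
  # classifier reproduces planted excitatory/inhibitory labels exactly
  measured <- vapply(wf$waveforms, function(w)
    waveform_features(w, fs)$tp_latency_ms, numeric(1))
  cls <- vapply(measured, classify_unit_type, character(1))
  planted <- ifelse(wf$info$tp_ms > 0.55, "Exc", "Int")
  expect_equal(unname(cls), planted)
})

test_that("pure-interneuron mixtures plant only sub-boundary latencies", {
  p <- sim_params(n_units = 30, seed = 8,
                  class_mix = c(Exc = 0, Int = 1, activated = 0))
  wf <- generate_unit_waveforms(p)
  fs <- attr(wf$waveforms, "fs")
  tps <- vapply(wf$waveforms, function(w)
    waveform_features(w, fs)$tp_latency_ms, numeric(1))
  expect_true(all(tps < 0.55))
})

test_that("complete thinning empties the suppression window", {
  p <- sim_params(seed = 9)
  p$conn_params <- list(n_connected = 3, n_independent = 0, delay_ms = 5,
                        window_ms = 3, suppression = 1, rate_hz = 15,
                        duration_s = 300)
  cs <- generate_connected_trains(p)
  for (k in seq_len(nrow(cs$truth))) {
    pre <- cs$trains[[cs$truth$pre_id[k]]]
    post <- cs$trains[[cs$truth$post_id[k]]]
    lag_hit <- (findInterval(post - 0.005, pre) -
                  findInterval(post - 0.008, pre)) > 0
    expect_equal(sum(lag_hit), 0)
  }
})

test_that("zero suppression gives a flat correlogram", {
  p <- sim_params(seed = 10)
  p$conn_params <- list(n_connected = 1, n_independent = 0, delay_ms = 5,
                        window_ms = 4, suppression = 0, rate_hz = 10,
                        duration_s = 1200)
  cs <- generate_connected_trains(p)
  cc <- compute_ccg(cs$trains[[1]], cs$trains[[2]])
  expected <- length(cs$trains[[1]]) * length(cs$trains[[2]]) * 0.001 / 1200
  expect_true(all(abs(cc$counts - expected) < 4 * sqrt(expected)))
})

test_that("degenerate feature clusters are recovered perfectly", {
  pr <- default_celltype_profile()
  pr$sd[] <- 1e-6
  p <- sim_params(seed = 11, celltype_profile = pr)
  ft <- generate_feature_table(p)
  model <- fit_celltype_model(ft$features)
  asg <- assign_celltype(model, ft$features)
  expect_equal(asg$label, ft$labels)
})

test_that("intracellular pair recovers intervals exactly without noise", {
  p <- sim_params(seed = 12, duration_s = 200, ic_noise_mv = 0,
                  ic_gamma_amp = 0)
  set.seed(slowosc:::child_seed(12, 1))
  rec_iv <- slowosc:::generate_state_sequence(p)
  truth <- list(upstate_intervals = rec_iv)
  pair <- generate_intracellular_pair(truth, p)
  ev <- detect_upstates_invitro(pair$cell1, pair$cell2)
  m <- match_intervals(ev, rec_iv, 0.1)
  expect_equal(m$f1, 1)
})

test_that("zero depolarization amplitude yields no in vitro events", {
  p <- sim_params(seed = 13, duration_s = 200, ic_amp_mv = 0)
  truth <- list(upstate_intervals = data.frame(start_s = c(50, 100),
                                               end_s = c(50.5, 100.5)))
  pair <- generate_intracellular_pair(truth, p)
  ev <- detect_upstates_invitro(pair$cell1, pair$cell2)
  expect_equal(nrow(ev), 0)
})
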