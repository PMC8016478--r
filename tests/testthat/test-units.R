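test_that("quality control passes clean units and flags violations", {
  set.seed(20)
  times <- cumsum(runif(500, 0.05, 0.2))
  amps <- rnorm(500, 100, 10)
  q <- qc_unit(times, amps)
  expect_true(q$pass)
  expect_lt(q$violation_frac, 0.05)
  expect_lt(q$missing_frac, 0.15)

  # 10% refractory violations -> fail
  viol <- sort(c(times, times[1:50] + 0.001))
  qv <- qc_unit(viol, rnorm(length(viol), 100, 10))
  expect_false(qv$pass)
  expect_match(qv$reason, "refractory")

  qf <- qc_unit(1:10, rnorm(10, 100, 10))
  expect_false(qf$pass)
  expect_equal(qf$reason, "too_few_spikes")
})

test_that("threshold-truncated amplitudes give ~50% estimated missing mass", {
  # amplitudes are the upper half of N(100, 15): a Gaussian fitted to the
  # histogram should place half its mass below the observed minimum
  set.seed(21)
  amps <- abs(rnorm(3000, 0, 15)) + 100
  times <- cumsum(runif(3000, 0.05, 0.2))
  q <- qc_unit(times, amps)
  expect_false(q$pass)
  expect_match(q$reason, "missing")
  expect_lt(abs(q$missing_frac - 0.5), 0.1)
})

test_that("waveform features measure trough-to-peak and repolarization", {
  fs <- 20000
  t <- seq(0, 4, by = 1000 / fs)  # ms grid
  w <- -100 * exp(-(t - 1.0)^2 / (2 * 0.01)) +
    40 * exp(-(t - 1.8)^2 / (2 * 0.04))
  f <- waveform_features(w, fs)
  expect_lt(abs(f$tp_latency_ms - 0.8), 0.05 + 1e-9)
  expect_gt(f$repolarization_time_ms, 0)
  expect_error(waveform_features(abs(w) + 1, fs), "trough")
})

test_that("the 0.55 ms boundary classifies with ties to interneurons", {
  expect_equal(classify_unit_type(0.60), "Exc")
  expect_equal(classify_unit_type(0.50), "Int")
  expect_equal(classify_unit_type(0.55), "Int")
})

test_that("drug response needs 2 sigma above baseline for 5 of 25 minutes", {
  inj <- 600
  base <- regular_train(5, 0, inj)  # perfectly steady baseline -> sd 0
  # steady unit: never crosses -> non-activated
  steady <- c(base, regular_train(5, inj, inj + 1500))
  r0 <- classify_drug_response(steady, inj)
  expect_equal(r0$response, "non-activated")

  set.seed(22)
  noisy_base <- sort(runif(3000, 0, inj))  # Poisson-ish baseline, sd > 0
  mk_eval <- function(high_min) {
    c(noisy_base,
      sort(runif(50 * 60 * high_min, inj, inj + high_min * 60)),
      sort(runif(100, inj + high_min * 60, inj + 1500)))
  }
  r6 <- classify_drug_response(mk_eval(6), inj)
  expect_equal(r6$response, "activated")
  expect_gte(r6$suprathreshold_min, 5)
  r4 <- classify_drug_response(mk_eval(4), inj)
  expect_equal(r4$response, "non-activated")

  # rescaling invariance: the decision only depends on rate shape
  tr <- mk_eval(6)
  dense <- sort(c(tr, tr + 0.001, tr + 0.002))  # 3x the rate everywhere
  expect_equal(classify_drug_response(dense, inj)$response, r6$response)

  # zero baseline SD with nonzero rates is flagged degenerate
  rd <- classify_drug_response(steady, inj)
  expect_true(rd$degenerate)
  expect_error(classify_drug_response(1:10, 100), "baseline")
})

test_that("cohort summary reports the activated fraction and TP ordering", {
  units <- data.frame(
    response = c(rep("activated", 31), rep("non-activated", 324)),
    class = c(rep("Int", 31), rep("Exc", 200), rep("Int", 124)),
    tp_latency_ms = c(runif(31, 0.45, 0.65), runif(200, 0.6, 1.1),
                      runif(124, 0.2, 0.5)))
  s <- response_population_summary(units)
  expect_equal(s$n_activated, 31)
  expect_equal(s$n_total, 355)
  expect_equal(s$fraction, 31 / 355)
  expect_equal(round(s$fraction, 3), 0.087)
  none <- units
  none$response <- "non-activated"
  expect_equal(response_population_summary(none)$fraction, 0)
})

test_that("every qc-passing unit receives exactly one class and one response", {
  p <- sim_params(seed = 23, duration_s = 2100, n_channels = 1, n_units = 30,
                  drug_onset_s = 600)
  rec <- generate_so_recording(p)
  fs <- attr(rec$waveforms, "fs")
  for (id in names(rec$trains)) {
    q <- qc_unit(rec$trains[[id]], rec$amplitudes[[id]])
    if (!q$pass) next
    tp <- waveform_features(rec$waveforms[[id]], fs)$tp_latency_ms
    cls <- classify_unit_type(tp)
    expect_true(cls %in% c("Exc", "Int"))
    resp <- classify_drug_response(rec$trains[[id]], 600)$response
    expect_true(resp %in% c("activated", "non-activated"))
  }
})

test_that("planted activated fraction is recovered exactly by classification", {
  p <- sim_params(seed = 24, duration_s = 2100, n_channels = 1, n_units = 40,
                  drug_onset_s = 600,
                  class_mix = c(Exc = 0.7, Int = 0.2, activated = 0.1))
  rec <- generate_so_recording(p)
  resp <- vapply(names(rec$trains), function(id)
    classify_drug_response(rec$trains[[id]], 600)$response, character(1))
  planted <- rec$units$class == "activated"
  expect_equal(unname(resp == "activated"), unname(planted))
})
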