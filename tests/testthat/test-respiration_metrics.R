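test_that("pure sinusoids are estimated at their exact frequency", {
  fs <- 400
  t <- seq(0, 10, by = 1 / fs)
  for (f in c(2.5, 5)) {
    est <- estimate_resp_frequency(sin(2 * pi * f * t), fs)
    expect_true(all(abs(est$frequency - f) < 0.02))
  }
})

test_that("the estimator is exactly amplitude-invariant", {
  fs <- 400
  set.seed(1)
  x <- sin(2 * pi * 6 * seq(0, 5, by = 1 / fs)) + 0.2 * rnorm(5 * fs + 1)
  a <- estimate_resp_frequency(x, fs)
  b <- estimate_resp_frequency(17.3 * x, fs)
  expect_equal(a$frequency, b$frequency, tolerance = 1e-9)
})

test_that("sinusoid error stays below one autocorrelation lag quantum across 1.5-13 Hz", {
  fs <- 400
  t <- seq(0, 4, by = 1 / fs)
  for (f in seq(1.5, 13, by = 0.5)) {
    est <- estimate_resp_frequency(sin(2 * pi * f * t), fs)
    quantum <- f^2 / fs   # df from a one-sample change in peak lag
    expect_lt(max(abs(est$frequency - f)), quantum + 1e-6)
  }
})

test_that("rolling estimates track a linear chirp", {
  fs <- 400
  dur <- 10
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  k <- (10 - 4) / dur
  x <- -cos(2 * pi * (4 * t + k * t^2 / 2))
  est <- estimate_resp_frequency(x, fs)
  truth <- 4 + k * est$window_center
  err <- abs(est$frequency - truth)
  expect_lt(mean(err, na.rm = TRUE), 0.5)
})

test_that("constant windows yield missing values with a warning", {
  fs <- 400
  x <- c(rep(0, 2 * fs), sin(2 * pi * 5 * seq(0, 2, by = 1 / fs)))
  expect_warning(est <- estimate_resp_frequency(x, fs), "constant")
  expect_true(any(is.na(est$frequency)))
  expect_true(any(!is.na(est$frequency)))
})

test_that("troughs of a sine are detected at its minima", {
  fs <- 400
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  pk <- detect_inhalation_peaks(sin(2 * pi * 5 * t), fs)
  expected <- seq(0.15, 9.8, by = 0.2)
  covered <- expected[expected > 0.5 & expected < 9.5]
  for (e in covered) expect_lt(min(abs(pk$peak_times - e)), 1.5 / fs)
})

test_that("generator inhalations are recovered within 5 ms despite noise", {
  sch <- state_schedule("NREM", 0, 60,
                        params = list(NREM = list(freq = 4.5, freq_jitter = 0.2,
                                                  amp = 1, amp_jitter = 0.05)))
  r <- generate_respiration(sch, fs = 400, seed = 8, noise_sd = 0.1)
  pk <- detect_inhalation_peaks(r$channel, 400)
  truth <- r$truth$inhalation_times
  truth <- truth[truth > 1 & truth < 59]
  d <- vapply(truth, function(tt) min(abs(pk$peak_times - tt)), numeric(1))
  expect_gte(mean(d <= 0.005), 0.95)
})

test_that("white noise yields a near-empty peak train", {
  set.seed(2)
  pk <- detect_inhalation_peaks(rnorm(30 * 400), 400)
  # a genuine 5 Hz rhythm would give ~150 troughs over 30 s
  expect_lt(length(pk$peak_times), 30)
})

test_that("relative error reproduces the printed formula", {
  same <- make_freq_series(rep(5, 100))
  out <- relative_error(same, same)
  expect_equal(out$per_trial_mean_error, 0)
  expect_equal(out$population_sd, 0)
  th <- make_freq_series(rep(5.2, 100))
  fl <- make_freq_series(rep(5.0, 100))
  expect_equal(relative_error(th, fl)$population_mean, 0.04, tolerance = 1e-12)
})

test_that("population statistics recover a constructed error distribution", {
  set.seed(21)
  eps <- rnorm(21, 0.016, 0.009)
  fl <- lapply(1:21, function(i) make_freq_series(rep(5, 200)))
  th <- lapply(1:21, function(i) make_freq_series(rep(5 * (1 + eps[i]), 200)))
  out <- relative_error(th, fl)
  expect_equal(out$population_mean, mean(eps), tolerance = 1e-9)
  expect_equal(out$population_sd, sd(eps), tolerance = 1e-9)
  expect_lt(abs(out$population_mean - 0.016), 0.006)
  expect_lt(abs(out$population_sd - 0.009), 0.006)
})

test_that("missing flow windows are excluded and counted", {
  fl <- make_freq_series(c(rep(5, 50), rep(NA, 10), rep(5, 40)))
  th <- make_freq_series(rep(5.1, 100))
  out <- relative_error(th, fl)
  expect_equal(out$n_excluded_windows, 10L)
  expect_equal(out$population_mean, 0.02, tolerance = 1e-12)
})

test_that("peak lag follows the flow-minus-thoracic sign convention", {
  fl <- make_peaks(seq(1, 20, by = 0.25))
  expect_equal(peak_lag(fl, fl)$mean_lag, 0)
  th <- make_peaks(fl$peak_times + 0.06)
  out <- peak_lag(fl, th)
  expect_equal(out$mean_lag, -0.06, tolerance = 1e-9)
  # thoracic missing every third peak: those flow peaks stay unpaired
  th2 <- make_peaks(fl$peak_times[-seq(3, length(fl$peak_times), by = 3)] + 0.01)
  out2 <- peak_lag(fl, th2)
  expect_equal(out2$n_unpaired_flow,
               length(seq(3, length(fl$peak_times), by = 3)))
  expect_error(peak_lag(fl, make_peaks(fl$peak_times + 500)), "not concurrent")
})

test_that("bout trials are aligned, baselined, and filtered by the 3-s rule", {
  freq <- make_freq_series(rep(6, 400), start = 0.5)   # 20 s of windows
  freq$frequency[freq$window_center >= 10 & freq$window_center < 13] <- 11
  bouts <- event_track("exploration_bout", c(2, 10), c(3, 13))
  tr <- extract_bout_trials(freq, bouts)
  expect_equal(tr$n_discarded_short, 1L)    # bout at 2 s: < 3 s of baseline
  expect_equal(tr$baseline_frequency, 6, tolerance = 1e-9)
  expect_equal(tr$exploration_frequency, 11, tolerance = 1e-9)
  expect_equal(tr$delta_frequency, 5, tolerance = 1e-9)
})

test_that("injected bout frequency increases are recovered from sessions", {
  n_b <- 20
  starts <- 10 + (0:(n_b - 1)) * 12
  sch <- state_schedule("wake", 0, max(starts) + 10,
                        params = list(wake = list(freq = 6, freq_jitter = 0.4,
                                                  amp = 1, amp_jitter = 0.1)))
  bouts <- event_track(rep("exploration_bout", n_b), starts, starts + 2)
  r <- generate_respiration(sch, bouts, fs = 400, seed = 13,
                            bout_increment = 3, noise_sd = 0.05)
  freq <- estimate_resp_frequency(r$channel, 400)
  tr <- extract_bout_trials(freq, bouts)
  expect_equal(length(tr$delta_frequency), n_b)
  expect_lt(abs(mean(tr$delta_frequency) - 3), 0.3)
  expect_lt(t.test(tr$exploration_frequency, tr$baseline_frequency,
                   paired = TRUE)$p.value, 0.05)
})

test_that("intersniff intervals are assigned to the earlier peak's state", {
  pk <- make_peaks(seq(0.1, 49.9, by = 0.2))
  hyp <- make_hypnogram(rep("NREM", 10))
  out <- intersniff_stats(pk, hyp)
  expect_equal(unname(out$mean_frequency["NREM"]), 5, tolerance = 1e-9)
  expect_true(all(abs(out$intervals$NREM - 0.2) < 1e-9))
  # a peak at 4.9 and the next at 5.1 straddle the epoch boundary at 5 s:
  # the interval belongs to the first epoch's state
  pk2 <- make_peaks(c(4.9, 5.1, 5.3))
  hyp2 <- make_hypnogram(c("wake", "NREM"))
  out2 <- intersniff_stats(pk2, hyp2)
  expect_equal(length(out2$intervals$wake), 1)
  expect_equal(out2$intervals$wake, 0.2, tolerance = 1e-9)
})

test_that("per-state mean frequencies are recovered from generated sessions", {
  segs <- state_schedule(c("wake", "REM", "wake", "REM"),
                         c(0, 30, 60, 90), c(30, 60, 90, 120),
                         params = list(wake = list(freq = 7, freq_jitter = 0.3),
                                       REM = list(freq = 3, freq_jitter = 0.2)))
  r <- generate_respiration(segs, fs = 400, seed = 14, noise_sd = 0.05)
  pk <- detect_inhalation_peaks(r$channel, 400)
  hyp <- make_hypnogram(rep(c("wake", "REM"), each = 6, times = 2))
  out <- intersniff_stats(pk, hyp)
  expect_lt(abs(out$mean_frequency["wake"] - 7), 0.3)
  expect_lt(abs(out$mean_frequency["REM"] - 3), 0.3)
})
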