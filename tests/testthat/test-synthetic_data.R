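test_that("constant-rate NREM respiration has exact 0.2-s intersniff intervals", {
  sch <- state_schedule("NREM", 0, 20,
                        params = list(NREM = list(freq = 5, freq_jitter = 0,
                                                  amp = 1, amp_jitter = 0)))
  r <- generate_respiration(sch, fs = 400, seed = 1)
  expect_equal(diff(r$truth$inhalation_times),
               rep(0.2, length(r$truth$inhalation_times) - 1),
               tolerance = 1e-9)
  expect_true(all(r$truth$frequency == 5))
})

test_that("bout increments raise the true instantaneous frequency exactly", {
  sch <- state_schedule("wake", 0, 30,
                        params = list(wake = list(freq = 6, freq_jitter = 0)))
  b <- event_track("exploration_bout", 10, 15)
  r <- generate_respiration(sch, b, fs = 400, seed = 2, bout_increment = 5)
  tt <- (seq_along(r$channel) - 1) / 400
  expect_true(all(r$truth$frequency[tt >= 10 & tt < 15] == 11))
  expect_true(all(r$truth$frequency[tt < 10 | tt >= 15] == 6))
  expect_error(generate_respiration(sch, event_track("exploration_bout", 25, 35),
                                    fs = 400, seed = 2),
               "bout outside session")
})

test_that("generation is deterministic in the seed and varies across seeds", {
  sch <- state_schedule("wake", 0, 10)
  a <- generate_respiration(sch, fs = 400, seed = 5)
  b <- generate_respiration(sch, fs = 400, seed = 5)
  c <- generate_respiration(sch, fs = 400, seed = 6)
  expect_identical(a$channel, b$channel)
  expect_false(identical(a$channel, c$channel))
})

test_that("truth inhalation times sit on the troughs of the noise-free channel", {
  sch <- state_schedule("NREM", 0, 30,
                        params = list(NREM = list(freq = 4, freq_jitter = 0.3,
                                                  amp = 1, amp_jitter = 0)))
  r <- generate_respiration(sch, fs = 400, seed = 3)
  idx <- round(r$truth$inhalation_times * 400) + 1
  idx <- idx[idx > 1 & idx < length(r$channel)]
  # trough: no neighbouring sample is lower by more than discretization slack
  for (i in idx) {
    expect_lt(r$channel[i], min(r$channel[c(i - 2, i + 2)]) + 1e-6)
  }
})

test_that("mixing weights imply the target coherence in closed form", {
  sch <- state_schedule("wake", 0, 60,
                        params = list(wake = list(freq = 9, freq_jitter = 0.5)))
  r <- generate_respiration(sch, fs = 400, seed = 4)
  ee_r <- generate_coupled_eeg_emg(r$channel,
                                   coupling_spec(list(alpha = list(eeg1_resp = 0.6))),
                                   fs = 400, seed = 4, broadband = 0)
  expect_equal(ee_r$truth$bands$alpha$eeg1_resp$coherence, 0.6,
               tolerance = 1e-9)
  ee_p <- generate_coupled_eeg_emg(r$channel,
                                   coupling_spec(list(alpha = list(eeg1_eeg2 = 0.6))),
                                   fs = 400, seed = 4, broadband = 0)
  expect_equal(ee_p$truth$bands$alpha$eeg1_eeg2$coherence, 0.6,
               tolerance = 1e-9)
  expect_error(coupling_spec(list(alpha = list(eeg1_resp = 1))),
               "unattainable")
})

test_that("estimated stationary coherence matches the implied value within 0.05", {
  sch <- state_schedule("wake", 0, 600,
                        params = list(wake = list(freq = 9, freq_jitter = 0.5)))
  r <- generate_respiration(sch, fs = 400, seed = 11)
  spec <- coupling_spec(list(alpha = list(eeg1_eeg2 = 0.6)))
  ee <- generate_coupled_eeg_emg(r$channel, spec, fs = 400, seed = 11,
                                 broadband = 0.3)
  X <- cbind(ee$eeg1, ee$eeg2, ee$emg, r$channel)
  pb <- pooled_band_pcoh(X, 400, "alpha", epoch_length = 4, weight = 0)
  expect_lt(abs(pb$coherence[1, 2] - ee$truth$bands$alpha$eeg1_eeg2$coherence),
            0.05)
})

test_that("zero coupling yields near-zero long-run coherence in every band", {
  sch <- state_schedule("wake", 0, 240)
  r <- generate_respiration(sch, fs = 400, seed = 12)
  ee <- generate_coupled_eeg_emg(r$channel, coupling_spec(), fs = 400,
                                 seed = 12)
  X <- cbind(ee$eeg1, ee$eeg2, ee$emg, r$channel)
  for (band in c("delta", "theta", "alpha", "beta")) {
    pb <- pooled_band_pcoh(X, 400, band, epoch_length = 2, weight = 0)
    expect_lt(pb$coherence[1, 2], 0.06)   # EEG1-EEG2
    expect_lt(pb$coherence[1, 4], 0.06)   # EEG1-Resp
  }
})

test_that("EMG bursts scale the in-interval RMS by the burst gain", {
  sch <- state_schedule("wake", 0, 40)
  r <- generate_respiration(sch, fs = 400, seed = 6)
  mv <- event_track("exploration_bout", 10, 20)
  ee <- generate_coupled_eeg_emg(r$channel, coupling_spec(), movement = mv,
                                 fs = 400, seed = 6, burst_gain = 10)
  tt <- (seq_along(ee$emg) - 1) / 400
  rms_in <- sqrt(mean(ee$emg[tt >= 10 & tt < 20]^2))
  rms_out <- sqrt(mean(ee$emg[tt < 10 | tt >= 20]^2))
  expect_equal(rms_in / rms_out, 10, tolerance = 0.1)
})

test_that("planned approaches produce matching truth bouts and trajectories", {
  tb <- generate_tracking_and_bouts(approach_plan = data.frame(time = 10,
                                                               dwell = 2),
                                    duration = 30, seed = 2)
  expect_equal(nrow(tb$truth$bouts), 1)
  expect_equal(tb$truth$bouts$end - tb$truth$bouts$start, 2)
  det <- detect_exploration_bouts(tb$tracking, c(12, 0))
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$start - 10), 1 / 25 + 1e-9)
  expect_lt(abs(det$end - 12), 1 / 25 + 1e-9)

  far <- generate_tracking_and_bouts(approach_plan = NULL, duration = 20,
                                     seed = 3)
  expect_equal(nrow(far$truth$bouts), 0)
  expect_equal(nrow(detect_exploration_bouts(far$tracking, c(12, 0))), 0)
  v <- compute_velocity(far$tracking)
  expect_lt(median(v$speed), 2)
})

test_that("session composition exports the configured structure", {
  s <- generate_session(list(duration = 60,
                             approach_plan = data.frame(time = c(10, 25, 40),
                                                        dwell = c(2, 2, 3)),
                             bout_coupling_delta = list(alpha = list(eeg1_eeg2 = 0.2))),
                        seed = 9)
  expect_equal(nrow(s$truth$bouts), 3)
  expect_equal(s$truth$coupling$alpha$eeg1_eeg2$bout_level, 0.2)
  expect_error(generate_session(list(durations = 60)), "unknown config keys")
})

test_that("sleep sessions follow the odor-trial window layout", {
  s <- generate_session(list(condition = "sleep_odor", duration = 120,
                             nrem_onset = 30), seed = 10)
  expect_equal(s$truth$odor_time, 50)          # NREM onset + 10 s + 10 s
  expect_equal(s$truth$sensor_window, c(40, 100))
  seg <- valid_segments(s$record)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start_time, seg$end_time), c(40, 100))
  # respiration steps up at odor time in the ground truth
  tt <- (seq_along(s$frequency) - 1) / 400
  pre <- mean(s$frequency[tt >= 45 & tt < 50])
  post <- mean(s$frequency[tt >= 50 & tt < 55])
  expect_gt(post - pre, 1.5)
})
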