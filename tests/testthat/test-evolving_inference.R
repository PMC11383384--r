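coupled_session <- function(events, duration, base = 0.4, delta = 0.2,
                            band = "delta", seed = 1, freq = 3,
                            broadband = 0.1) {
  sch <- state_schedule("wake", 0, duration,
                        params = list(wake = list(freq = freq,
                                                  freq_jitter = 0.3)))
  r <- generate_respiration(sch, events, fs = 400, seed = seed,
                            bout_increment = 0)
  lv <- list(); lv[[band]] <- list(eeg1_eeg2 = base)
  dl <- list(); dl[[band]] <- list(eeg1_eeg2 = delta)
  ee <- generate_coupled_eeg_emg(r$channel, coupling_spec(lv, dl),
                                 fs = 400, seed = seed, bouts = events,
                                 broadband = broadband)
  make_record(cbind(ee$eeg1, ee$eeg2, ee$emg, r$channel))
}

test_that("stationary coupling gives trendless epoch series at the right level", {
  rec <- coupled_session(NULL, 180, base = 0.4, delta = 0, seed = 21)
  pc <- evolving_pcoh(rec, "delta")
  d <- pc[pc$pair == "EEG1-EEG2", ]
  expect_lt(abs(mean(d$estimate_debiased) - 0.4), 0.08)
  fit <- lm(estimate_debiased ~ epoch_start, data = d)
  ci <- confint(fit)["epoch_start", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_true(all(d$estimate >= 0 & d$estimate <= 1))
})

test_that("a coupling step at 60 s is detected by the epoch series", {
  step <- event_track("exploration_bout", 60, 120)
  rec <- coupled_session(step, 120, base = 0.3, delta = 0.3, seed = 22)
  pc <- evolving_pcoh(rec, "delta")
  d <- pc[pc$pair == "EEG1-EEG2", ]
  pre <- d$estimate_debiased[d$epoch_start < 60]
  post <- d$estimate_debiased[d$epoch_start >= 60]
  expect_lt(t.test(pre, post)$p.value, 0.01)
  expect_gt(mean(post) - mean(pre), 0.15)
})

test_that("masked intervals produce no overlapping epochs in the series", {
  n <- 120 * 400
  mask <- rep(FALSE, n)
  mask[(40 * 400 + 1):(70 * 400)] <- TRUE
  set.seed(23)
  rec <- make_record(matrix(rnorm(4 * n), ncol = 4), gap_mask = mask)
  pc <- evolving_pcoh(rec, "theta")
  ep <- attr(pc, "epoch_length")
  expect_true(all(pc$epoch_start + ep <= 40 + 1e-6 | pc$epoch_start >= 70))
})

test_that("lag regression is null on constant-coupling sessions", {
  rec <- coupled_session(NULL, 420, base = 0.4, delta = 0, seed = 24)
  pc <- evolving_pcoh(rec, "delta")
  ev <- snapped_events(15, 25, "delta")
  lr <- lagged_event_regression(pc, ev)
  expect_true(all(abs(lr$estimate) < 0.15))
  expect_lte(mean(lr$p_value < 0.05), 0.25)
})

test_that("an injected lag-0 coupling change is recovered with the right profile", {
  ev <- snapped_events(30, 20, "delta")
  rec <- coupled_session(ev, max(ev$end) + 30, base = 0.4, delta = 0.2,
                         seed = 25)
  pc <- evolving_pcoh(rec, "delta")
  lr <- lagged_event_regression(pc, ev)
  d <- lr[lr$pair == "EEG1-EEG2", ]
  expect_gt(d$estimate[d$lag == 0], 0.1)
  expect_lt(abs(d$estimate[d$lag == -3]), 0.1)
  expect_lt(abs(d$estimate[d$lag == -2]), 0.1)
  expect_lt(d$p_value[d$lag == 0], 0.05)
})

test_that("opposite-signed injections in two bands are both recovered", {
  # emulates the exploration pattern: delta coupling falls, alpha rises
  ev <- snapped_events(30, 20, "delta")
  ev$end <- ev$start + 5          # long bouts cover epochs of both bands
  sch <- state_schedule("wake", 0, max(ev$end) + 30,
                        params = list(wake = list(freq = 3, freq_jitter = 0.3)))
  r <- generate_respiration(sch, ev, fs = 400, seed = 26, bout_increment = 0)
  spec <- coupling_spec(list(delta = list(eeg1_eeg2 = 0.45),
                             alpha = list(eeg1_eeg2 = 0.2)),
                        list(delta = list(eeg1_eeg2 = -0.15),
                             alpha = list(eeg1_eeg2 = 0.15)))
  ee <- generate_coupled_eeg_emg(r$channel, spec, fs = 400, seed = 26,
                                 bouts = ev, broadband = 0.1)
  rec <- make_record(cbind(ee$eeg1, ee$eeg2, ee$emg, r$channel))
  # events sit on the delta epoch grid; for the short alpha epochs the
  # bout response lands on the lags following onset
  pc_d <- evolving_pcoh(rec, "delta")
  lr_d <- lagged_event_regression(pc_d, ev)
  dd <- lr_d[lr_d$pair == "EEG1-EEG2", ]
  expect_lt(dd$estimate[dd$lag == 0], -0.05)
  pc_a <- evolving_pcoh(rec, "alpha")
  lr_a <- lagged_event_regression(pc_a, ev)
  da <- lr_a[lr_a$pair == "EEG1-EEG2", ]
  expect_gt(mean(da$estimate[da$lag %in% 1:3]), 0.05)
})

test_that("the graph edge rule reproduces the printed thresholds on a grid", {
  grid <- expand.grid(est = c(0, 0.1, 0.15, 0.1500001, 0.3, 0.8),
                      p = c(0.001, 0.049, 0.05, 0.2, 1))
  rule <- graph_edge_rule(grid$est, grid$p)
  expect_identical(rule$drawn, grid$est > 0.15)
  expect_identical(rule$significant, grid$est > 0.15 & grid$p < 0.05)
})

test_that("connectivity graphs pool still epochs and omit absent couplings", {
  s <- generate_session(list(duration = 240,
                             approach_plan = data.frame(time = c(60, 150),
                                                        dwell = c(5, 5)),
                             couplings = list(theta = list(eeg1_eeg2 = 0.5))),
                        seed = 27)
  mt <- classify_movement(channel(s$record, "EMG"), 400)
  g <- build_connectivity_graph(s$record, "theta", mt)
  expect_gt(g$n_still_epochs, 10)
  e12 <- g$edges[g$edges$pair == "EEG1-EEG2", ]
  expect_true(e12$drawn && e12$significant)
  # respiration was generated independent of the EMG channel
  er <- g$edges[g$edges$pair == "EMG-Resp", ]
  expect_false(er$drawn)
  expect_error(build_connectivity_graph(s$record, "theta",
                                        transform(mt, moving = TRUE)),
               "no still epochs")
})

test_that("the mixed model separates within-animal coupling from confounds", {
  dn <- generate_emg_sniff_bins(2000, 4, correlation = 0,
                                intercept_sd = 0.1, emg_shift_sd = 2,
                                confound = 1, seed = 3)
  pooled <- stats::cor(dn$sniff_rate, dn$emg_rms)
  expect_gt(pooled, 0.5)     # the pooled correlation is fooled
  m0 <- emg_resp_mixed_model(dn$sniff_rate, dn$emg_rms, dn$animal_id)
  expect_lt(abs(m0$correlation), 0.1)
  expect_gt(m0$p_value, 0.05)

  d <- generate_emg_sniff_bins(1500, 4, correlation = 0.5, seed = 2)
  m <- emg_resp_mixed_model(d$sniff_rate, d$emg_rms, d$animal_id)
  expect_lt(abs(m$correlation - 0.5), 0.1)
  expect_lt(m$p_value, 0.001)

  d1 <- generate_emg_sniff_bins(200, 1, correlation = 0.3, seed = 4)
  expect_warning(m1 <- emg_resp_mixed_model(d1$sniff_rate, d1$emg_rms,
                                            d1$animal_id), "single animal")
  ols <- unname(coef(lm(d1$sniff_rate ~ d1$emg_rms))[2])
  expect_equal(m1$coefficient, ols, tolerance = 1e-12)
  expect_error(emg_resp_mixed_model(d$sniff_rate, rep(1, nrow(d)),
                                    d$animal_id), "constant predictor")
})

test_that("subset analyses split bins by the movement flags", {
  d <- generate_emg_sniff_bins(1000, 4, correlation = 0.4, seed = 5)
  moving <- d$emg_rms > stats::median(d$emg_rms)
  m_all <- emg_resp_mixed_model(d$sniff_rate, d$emg_rms, d$animal_id)
  m_still <- emg_resp_mixed_model(d$sniff_rate, d$emg_rms, d$animal_id,
                                  subset = "still", moving = moving)
  m_mov <- emg_resp_mixed_model(d$sniff_rate, d$emg_rms, d$animal_id,
                                subset = "moving", moving = moving)
  expect_equal(m_still$n_bins + m_mov$n_bins, m_all$n_bins)
  expect_error(emg_resp_mixed_model(d$sniff_rate, d$emg_rms, d$animal_id,
                                    subset = "still"), "moving flags")
})
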