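# Synthetic session generator. Emulates the statistical structure the
# analysis assumes -- state- and behavior-dependent respiration, band-coupled
# EEG, burst EMG, arena trajectories -- and exports exact ground truth so
# every downstream estimator can be checked for parameter recovery.

# Single global seed feeding per-component streams: each named component
# draws from its own deterministic seed so components are individually
# reproducible no matter which subset of generators runs.
.component_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.truncnorm1 <- function(sd) {
  if (sd <= 0) return(0)
  repeat {
    z <- rnorm(1, 0, sd)
    if (abs(z) <= 3 * sd) return(z)
  }
}

#' Default per-state respiration parameters
#'
#' Wake: fast, variable, large-amplitude sniffing; NREM: slow, highly
#' regular, low amplitude; REM: slow with doubled frequency jitter and
#' amplitude jitter (irregular). Frequencies in Hz, jitter = SD of the
#' per-cycle frequency perturbation (truncated at 3 SD).
#'
#' @return Named list of per-state parameter lists.
#' @export
default_state_params <- function() {
  list(
    wake = list(freq = 7.0, freq_jitter = 1.0, amp = 1.0, amp_jitter = 0.30),
    NREM = list(freq = 3.2, freq_jitter = 0.15, amp = 0.6, amp_jitter = 0.05),
    REM  = list(freq = 3.1, freq_jitter = 0.30, amp = 0.7, amp_jitter = 0.15)
  )
}

#' Vigilance-state schedule for the generator
#'
#' @param state Character vector of states (`wake`, `NREM`, `REM`).
#' @param start,end Segment boundaries in seconds; segments must tile
#'   `[min(start), max(end))` without overlap.
#' @param params Per-state respiration parameters
#'   (see [default_state_params()]); partial overrides are merged.
#' @return An object of class `state_schedule`.
#' @export
state_schedule <- function(state, start, end, params = NULL) {
  stopifnot(length(state) == length(start), length(start) == length(end))
  if (!all(state %in% c("wake", "NREM", "REM")))
    stop("states must be wake/NREM/REM")
  o <- order(start)
  state <- state[o]; start <- start[o]; end <- end[o]
  if (any(end <= start)) stop("segment end must exceed start")
  if (length(start) > 1 && any(abs(start[-1] - end[-length(end)]) > 1e-9))
    stop("segments must tile the session without gaps or overlap")
  p <- default_state_params()
  for (s in names(params)) p[[s]] <- utils::modifyList(p[[s]], params[[s]])
  if (any(vapply(p, function(q) q$freq <= 0, logical(1))))
    stop("state frequencies must be positive")
  structure(list(segments = data.frame(state = state, start = start, end = end),
                 params = p),
            class = "state_schedule")
}

.state_at_samples <- function(schedule, t) {
  seg <- schedule$segments
  idx <- findInterval(t, seg$start)
  idx[idx < 1] <- 1
  seg$state[pmin(idx, nrow(seg))]
}

# asymmetric sniff cycle: inhalation (negative deflection, thoracic
# convention) occupies the first `asym` fraction of the cycle, exhalation
# the rest; the inhalation peak (trough) sits at phase asym/2.
.resp_shape <- function(frac, asym) {
  ifelse(frac < asym, -sin(pi * frac / asym), sin(pi * (frac - asym) / (1 - asym)))
}

#' Generate a respiration channel with exact ground truth
#'
#' Phase oscillator whose instantaneous frequency is the per-state mean,
#' plus a per-cycle Gaussian jitter (truncated at 3 SD), plus a fixed
#' increment inside exploration bouts. The cycle shape is asymmetric
#' (faster inhalation than exhalation) and the inhalation peak is the
#' cycle trough. Ground truth carries the exact per-sample frequency and
#' the exact inhalation times.
#'
#' @param schedule A [state_schedule()].
#' @param bouts Optional `event_track` of exploration bouts (frequency is
#'   raised by `bout_increment` inside them).
#' @param fs Sampling rate, Hz (>= 100).
#' @param seed Seed for the respiration component stream.
#' @param bout_increment Frequency increment inside bouts, Hz.
#' @param asymmetry Inhalation fraction of the cycle, in (0, 1).
#' @param noise_sd SD of additive white sensor noise (signal units).
#' @return List with `channel` (numeric vector), and `truth`: `frequency`
#'   (per sample, Hz), `inhalation_times` (s), `states` (per sample),
#'   `seed`.
#' @export
generate_respiration <- function(schedule, bouts = NULL, fs = 400, seed = 1,
                                 bout_increment = 5, asymmetry = 0.4,
                                 noise_sd = 0) {
  if (fs < 100) stop("fs must be at least 100 Hz")
  seg <- schedule$segments
  t0 <- seg$start[1]; t1 <- seg$end[nrow(seg)]
  n <- round((t1 - t0) * fs)
  tt <- t0 + (0:(n - 1)) / fs
  states <- .state_at_samples(schedule, tt)
  par <- schedule$params
  base <- vapply(par, function(p) p$freq, numeric(1))[states]
  jit_sd <- vapply(par, function(p) p$freq_jitter, numeric(1))[states]
  amp <- vapply(par, function(p) p$amp, numeric(1))[states]
  amp_jit <- vapply(par, function(p) p$amp_jitter, numeric(1))[states]
  if (!is.null(bouts) && nrow(bouts) > 0) {
    if (any(bouts$start < t0 - 1e-9) || any(bouts$end > t1 + 1e-9))
      stop("bout outside session")
    inb <- rep(FALSE, n)
    for (i in seq_len(nrow(bouts)))
      inb[tt >= bouts$start[i] & tt < bouts$end[i]] <- TRUE
    base <- base + bout_increment * inb
  }
  set.seed(.component_seed(seed, "respiration"))
  phase <- numeric(n)
  finst <- numeric(n)
  ampl <- numeric(n)
  i <- 1L
  cur <- 0            # phase at the *start* of sample i
  cycle0 <- 0         # integer phase at current cycle start
  repeat {
    j <- .truncnorm1(jit_sd[i])
    a <- max(amp[i] * (1 + .truncnorm1(amp_jit[i])), 0.05)
    # chunk generously sized to cover one cycle even at the lowest rate
    L <- min(n - i + 1L, as.integer(ceiling(1.6 * fs / max(base[i] + j, 0.5))) + 2L)
    idx <- i:(i + L - 1L)
    f <- pmax(base[idx] + j, 0.5)
    ph <- cur + cumsum(f) / fs
    hit <- which(ph >= cycle0 + 1)
    if (length(hit) == 0 && i + L - 1L < n) {
      # extremely slow cycle: extend chunk
      L2 <- min(n - i + 1L, 4L * L)
      idx <- i:(i + L2 - 1L)
      f <- pmax(base[idx] + j, 0.5)
      ph <- cur + cumsum(f) / fs
      hit <- which(ph >= cycle0 + 1)
    }
    last <- if (length(hit)) hit[1] else length(idx)
    use <- idx[seq_len(last)]
    phase[use] <- ph[seq_len(last)]
    finst[use] <- f[seq_len(last)]
    ampl[use] <- a
    i <- use[length(use)] + 1L
    cur <- phase[use[length(use)]]
    if (length(hit)) cycle0 <- cycle0 + 1
    if (i > n) break
  }
  frac <- phase - floor(phase)
  x <- ampl * .resp_shape(frac, asymmetry)
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  # exact inhalation times: crossings of phase = k + asymmetry/2
  target <- floor(phase - asymmetry / 2)
  cross <- which(diff(target) >= 1) + 1L
  ph_prev <- phase[cross - 1L]
  ph_this <- phase[cross]
  goal <- floor(phase[cross] - asymmetry / 2) + asymmetry / 2
  fracx <- (goal - ph_prev) / (ph_this - ph_prev)
  inh <- tt[cross - 1L] + fracx / fs
  list(channel = x,
       truth = list(frequency = finst, inhalation_times = inh,
                    states = states, phase = phase, seed = seed))
}

#' Coupling specification for the EEG generator
#'
#' Target magnitude-squared coherence between each EEG channel and the
#' respiration channel, per band, plus an additive change applied inside
#' exploration bouts (clipped to `[0, 0.99]`).
#'
#' @param levels Named list, one entry per band name, each a list with any
#'   of `eeg1_resp`, `eeg2_resp`, `eeg1_eeg2` in `[0, 1)`.
#' @param bout_delta Same shape; additive change during bouts. Optional.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(levels = NULL, bout_delta = NULL) {
  zero <- list(eeg1_resp = 0, eeg2_resp = 0, eeg1_eeg2 = 0)
  base <- lapply(COHERENCE_BANDS, function(b) zero)
  for (b in names(levels)) {
    stopifnot(b %in% names(base))
    base[[b]] <- utils::modifyList(base[[b]], levels[[b]])
  }
  lv <- unlist(base)
  if (any(lv < 0 | lv > 1)) stop("coupling levels must lie in [0, 1]")
  if (any(lv >= 1))
    stop("unattainable coupling target: level 1 with nonzero independent noise")
  delta <- lapply(COHERENCE_BANDS, function(b) zero)
  for (b in names(bout_delta))
    delta[[b]] <- utils::modifyList(delta[[b]], bout_delta[[b]])
  structure(list(levels = base, bout_delta = delta), class = "coupling_spec")
}

# respiration-locked band carrier: keeps the respiration channel's Fourier
# phases inside the band but flattens the magnitude, so a channel mixed
# from it attains the same coherence with the respiration channel at every
# in-band frequency bin irrespective of the sniff line's spectral shape.
.band_carrier <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  F <- fft(x)
  freqs <- (0:(n - 1)) * fs / n
  pos <- which(freqs >= f_lo & freqs < f_hi & freqs <= fs / 2)
  U <- complex(n)
  mag <- Mod(F[pos])
  U[pos] <- ifelse(mag > 1e-12, F[pos] / mag, 1 + 0i)
  mirror <- n + 2 - pos
  ok <- mirror >= 1 & mirror <= n & mirror != pos
  U[mirror[ok]] <- Conj(U[pos[ok]])
  Re(fft(U, inverse = TRUE) / n)
}

# phase-randomized surrogate: identical power spectrum, independent phases
.phase_surrogate <- function(x) {
  n <- length(x)
  X <- fft(x)
  half <- 2:ceiling(n / 2)
  ph <- runif(length(half), 0, 2 * pi)
  X[half] <- Mod(X[half]) * exp(1i * ph)
  X[n + 2 - half] <- Conj(X[half])
  Re(fft(X, inverse = TRUE) / n)
}

.DEFAULT_BAND_GAINS <- list(
  wake = c(delta = 0.6, theta = 0.8, alpha = 0.8, beta = 0.6),
  NREM = c(delta = 3.5, theta = 0.5, alpha = 0.4, beta = 0.3),
  REM  = c(delta = 0.4, theta = 2.8, alpha = 0.5, beta = 0.3)
)
.DEFAULT_EMG_GAINS <- c(wake = 3, NREM = 1, REM = 0.3)

#' Generate EEG and EMG channels coupled to a respiration channel
#'
#' Each EEG channel is, per band, a weighted sum of a shared band-limited
#' component derived from the respiration channel (its in-band Fourier
#' phases with a flattened magnitude, so the attained coherence is uniform
#' across the band) and an independent band-limited noise of identical
#' spectrum (a phase-randomized surrogate), plus a broadband AR(1)
#' background. With unit-variance components and
#' mixing weight w against unit independent noise, the implied
#' magnitude-squared coherence is w^2 / (w^2 + 1 + s_bb) where s_bb is the
#' in-band broadband variance; weights are chosen from the target levels
#' and the implied coherences are exported in the truth. EMG is broadband
#' noise whose RMS is raised by `burst_gain` inside movement intervals
#' (and scaled per state when a schedule is given).
#'
#' @param resp Respiration channel (numeric vector).
#' @param spec A [coupling_spec()].
#' @param movement Optional `event_track`; EMG bursts inside its intervals.
#' @param fs Sampling rate, Hz.
#' @param seed Seed for the EEG/EMG component streams.
#' @param bouts Optional `event_track`; coupling modulated inside bouts by
#'   the spec's `bout_delta`.
#' @param schedule Optional [state_schedule()]; scales per-band EEG gains
#'   and EMG tone per state so vigilance scoring has signal to work with.
#' @param broadband SD of the AR(1) broadband background on each EEG channel.
#' @param emg_sd Baseline EMG noise SD.
#' @param burst_gain EMG RMS multiplier inside movement intervals.
#' @return List with `eeg1`, `eeg2`, `emg` and `truth` (weights, implied
#'   coherence per band and channel, EMG parameters).
#' @export
generate_coupled_eeg_emg <- function(resp, spec, movement = NULL, fs = 400,
                                     seed = 1, bouts = NULL, schedule = NULL,
                                     broadband = 0.3, emg_sd = 1,
                                     burst_gain = 10) {
  n <- length(resp)
  tt <- (0:(n - 1)) / fs
  set.seed(.component_seed(seed, "eeg"))
  for (b in names(spec$levels)) {
    bd <- band_definition(b)
    if (bd$f_hi >= fs / 2) stop("band above Nyquist: ", b)
  }
  ar_a <- 0.9
  bb1 <- as.numeric(stats::filter(rnorm(n), ar_a, method = "recursive"))
  bb2 <- as.numeric(stats::filter(rnorm(n), ar_a, method = "recursive"))
  bb1 <- broadband * bb1 / sd(bb1)
  bb2 <- broadband * bb2 / sd(bb2)
  st <- if (!is.null(schedule)) .state_at_samples(schedule, tt) else NULL
  eeg1 <- bb1; eeg2 <- bb2
  truth <- list(bands = list(), seed = seed)
  inb <- rep(FALSE, n)
  if (!is.null(bouts) && nrow(bouts) > 0)
    for (i in seq_len(nrow(bouts)))
      inb[tt >= bouts$start[i] & tt < bouts$end[i]] <- TRUE
  level_profile <- function(b, ch) {
    lev <- rep(spec$levels[[b]][[ch]], n)
    dlt <- spec$bout_delta[[b]][[ch]]
    if (dlt != 0) lev[inb] <- lev[inb] + dlt
    pmin(pmax(lev, 0), 0.99)
  }
  for (b in names(spec$levels)) {
    bd <- band_definition(b)
    gain <- rep(1, n)
    if (!is.null(st)) {
      g <- vapply(.DEFAULT_BAND_GAINS, function(x) x[[b]], numeric(1))
      gain <- unname(g[st])
    }
    lev1 <- level_profile(b, "eeg1_resp")
    lev2 <- level_profile(b, "eeg2_resp")
    lev12 <- level_profile(b, "eeg1_eeg2")
    resp_coupled <- any(lev1 > 0) || any(lev2 > 0)
    u <- NULL
    if (resp_coupled) {
      u <- .band_carrier(resp, fs, bd$f_lo, bd$f_hi)
      su <- sd(u)
      if (su < 1e-10)
        stop("unattainable coupling target: respiration has no power in band ", b)
      u <- u / su
    }
    # shared EEG1-EEG2 component: both channels carry weight a with
    # a^2 = sqrt(c) / (1 - sqrt(c)) so that a^4 / (a^2 + 1)^2 = c
    a12 <- sqrt(sqrt(lev12) / (1 - sqrt(lev12)))
    v <- bandpass_filter(rnorm(n), fs, bd$f_lo, bd$f_hi)
    v <- v / sd(v)
    sbb1 <- var(bandpass_filter(bb1, fs, bd$f_lo, bd$f_hi))
    sbb2 <- var(bandpass_filter(bb2, fs, bd$f_lo, bd$f_hi))
    w1 <- sqrt(lev1 / (1 - lev1))
    w2 <- sqrt(lev2 / (1 - lev2))
    for (chn in 1:2) {
      w <- if (chn == 1) w1 else w2
      if (resp_coupled) {
        # surrogate of the carrier keeps the independent noise spectrum
        # identical to the shared component's
        nt <- .phase_surrogate(u)
      } else {
        nt <- bandpass_filter(rnorm(n), fs, bd$f_lo, bd$f_hi)
      }
      nt <- nt / sd(nt)
      shared <- if (resp_coupled) w * u else 0
      comp <- gain * (shared + a12 * v + nt)
      if (chn == 1) eeg1 <- eeg1 + comp else eeg2 <- eeg2 + comp
    }
    imp <- function(w, a, sbb) w^2 / (w^2 + a^2 + 1 + sbb)
    imp12 <- function(w1, w2, a, s1, s2)
      (w1 * w2 + a^2)^2 /
        ((w1^2 + a^2 + 1 + s1) * (w2^2 + a^2 + 1 + s2))
    pick <- function(x, i) x[i]
    base_i <- which.min(lev1 + lev2 + lev12)[1]
    bout_i <- which.max(lev1 + lev2 + lev12)[1]
    truth$bands[[b]] <- list(
      eeg1_resp = list(level = spec$levels[[b]]$eeg1_resp,
                       bout_level = max(lev1), weight = w1[base_i],
                       coherence = imp(w1[base_i], a12[base_i], sbb1),
                       bout_coherence = imp(w1[bout_i], a12[bout_i], sbb1)),
      eeg2_resp = list(level = spec$levels[[b]]$eeg2_resp,
                       bout_level = max(lev2), weight = w2[base_i],
                       coherence = imp(w2[base_i], a12[base_i], sbb2),
                       bout_coherence = imp(w2[bout_i], a12[bout_i], sbb2)),
      eeg1_eeg2 = list(level = spec$levels[[b]]$eeg1_eeg2,
                       bout_level = max(lev12), weight = a12[base_i],
                       coherence = imp12(w1[base_i], w2[base_i], a12[base_i],
                                         sbb1, sbb2),
                       bout_coherence = imp12(w1[bout_i], w2[bout_i],
                                              a12[bout_i], sbb1, sbb2)))
  }
  set.seed(.component_seed(seed, "emg"))
  emg <- rnorm(n, 0, emg_sd)
  if (!is.null(st)) emg <- emg * unname(.DEFAULT_EMG_GAINS[st])
  if (!is.null(movement) && nrow(movement) > 0) {
    for (i in seq_len(nrow(movement))) {
      sel <- tt >= movement$start[i] & tt < movement$end[i]
      emg[sel] <- emg[sel] * burst_gain
    }
  }
  truth$emg <- list(sd = emg_sd, burst_gain = burst_gain)
  list(eeg1 = eeg1, eeg2 = eeg2, emg = emg, truth = truth)
}

#' Generate an arena trajectory with approach/retraction bouts
#'
#' Deterministic smooth nose trajectory given a plan of approach times and
#' dwell durations: the nose ramps in so that its distance to the object
#' crosses the 2 cm bout perimeter exactly at the planned bout start, dwells
#' at 1 cm, and ramps out crossing 2 cm exactly at the planned bout end.
#' Between approaches the mouse wanders at a distance far from the object.
#'
#' @param arena_radius Arena radius, cm (arena centred at the origin).
#' @param object_position Object centroid, cm (must lie inside the arena).
#' @param approach_plan Data frame with columns `time` (bout start, s) and
#'   `dwell` (bout duration, s); may have zero rows.
#' @param frame_rate Video frame rate, Hz.
#' @param duration Session duration, s.
#' @param seed Seed for the wander component.
#' @return List with `tracking` (a [tracking_trace()]), `events` (detected
#'   perimeter, as an `event_track`) and `truth` (`bouts` data frame).
#' @export
generate_tracking_and_bouts <- function(arena_radius = 25,
                                        object_position = c(12, 0),
                                        approach_plan = NULL,
                                        frame_rate = 25, duration = 60,
                                        seed = 1) {
  if (sqrt(sum(object_position^2)) >= arena_radius)
    stop("object must lie inside the arena")
  set.seed(.component_seed(seed, "tracking"))
  tt <- seq(0, duration - 1 / frame_rate, by = 1 / frame_rate)
  far <- min(15, arena_radius - 3)
  d <- far + 1.5 * sin(2 * pi * 0.03 * tt + runif(1, 0, 2 * pi))
  if (!is.null(approach_plan) && nrow(approach_plan) > 0) {
    for (i in seq_len(nrow(approach_plan))) {
      t0 <- approach_plan$time[i]; dw <- approach_plan$dwell[i]
      if (t0 - 1 < 0 || t0 + dw + 1 > duration)
        stop("approach plan entry outside session")
      pre <- tt >= t0 - 1 & tt < t0
      d[pre] <- approx(c(t0 - 1, t0), c(far, 2), xout = tt[pre])$y
      rampin <- tt >= t0 & tt < t0 + 0.2
      d[rampin] <- approx(c(t0, t0 + 0.2), c(2, 1), xout = tt[rampin])$y
      dwell <- tt >= t0 + 0.2 & tt < t0 + dw - 0.2
      d[dwell] <- 1
      rampout <- tt >= t0 + dw - 0.2 & tt < t0 + dw
      d[rampout] <- approx(c(t0 + dw - 0.2, t0 + dw), c(1, 2),
                           xout = tt[rampout])$y
      post <- tt >= t0 + dw & tt < t0 + dw + 1
      d[post] <- approx(c(t0 + dw, t0 + dw + 1), c(2, far), xout = tt[post])$y
    }
  }
  # bout perimeter is inclusive (<= 2 cm counts as inside): push the
  # boundary samples epsilon outside so the planned crossing frame is the
  # first frame strictly inside
  d <- d + 1e-9
  dirv <- -object_position / sqrt(sum(object_position^2))
  nose <- cbind(object_position[1] + d * dirv[1],
                object_position[2] + d * dirv[2])
  centre <- cbind(object_position[1] + (d + 3) * dirv[1],
                  object_position[2] + (d + 3) * dirv[2])
  tail_ <- cbind(object_position[1] + (d + 6) * dirv[1],
                 object_position[2] + (d + 6) * dirv[2])
  trace <- tracking_trace(tt, nose, centre, tail_, frame_rate)
  truth_bouts <- if (!is.null(approach_plan) && nrow(approach_plan) > 0) {
    data.frame(start = approach_plan$time,
               end = approach_plan$time + approach_plan$dwell)
  } else data.frame(start = numeric(), end = numeric())
  events <- if (nrow(truth_bouts) > 0) {
    event_track(rep("exploration_bout", nrow(truth_bouts)),
                truth_bouts$start, truth_bouts$end)
  } else event_track()
  list(tracking = trace, events = events, truth = list(bouts = truth_bouts))
}

#' Generate per-bin sniff-rate / EMG-RMS data across animals
#'
#' For the mixed-model confound check: per-animal random intercepts on the
#' sniff rate, optional per-animal EMG shifts, an optional confound tying
#' intercepts to EMG shifts (which fools a pooled correlation but not the
#' random-intercept model), and a controlled within-animal correlation
#' between EMG RMS and sniff rate.
#'
#' @param n_bins Total number of bins (split evenly across animals).
#' @param n_animals Number of animals.
#' @param correlation Target within-animal correlation in (-1, 1).
#' @param intercept_sd SD of the per-animal sniff-rate intercepts, Hz.
#' @param emg_shift_sd SD of per-animal EMG mean shifts.
#' @param confound Coefficient tying the sniff intercept to the animal's
#'   EMG shift (0 = none).
#' @param seed Seed.
#' @return Data frame with `animal_id`, `emg_rms`, `sniff_rate`, and the
#'   true `correlation` as an attribute.
#' @export
generate_emg_sniff_bins <- function(n_bins, n_animals = 4, correlation = 0,
                                    intercept_sd = 0.2, emg_shift_sd = 0,
                                    confound = 0, seed = 1) {
  stopifnot(abs(correlation) < 1)
  set.seed(.component_seed(seed, "emg_sniff_bins"))
  per <- ceiling(n_bins / n_animals)
  ids <- rep(sprintf("m%02d", seq_len(n_animals)), each = per)[seq_len(n_bins)]
  shift <- rnorm(n_animals, 0, emg_shift_sd)
  icpt <- 6 + confound * shift + rnorm(n_animals, 0, intercept_sd)
  j <- as.integer(factor(ids))
  emg <- shift[j] + rnorm(n_bins)
  beta <- correlation / sqrt(1 - correlation^2)
  sniff <- icpt[j] + beta * (emg - shift[j]) + rnorm(n_bins)
  out <- data.frame(animal_id = ids, emg_rms = emg, sniff_rate = sniff)
  attr(out, "correlation") <- correlation
  out
}

.SESSION_CONFIG_KEYS <- c("condition", "duration", "fs", "states",
                          "approach_plan", "bout_increment", "couplings",
                          "bout_coupling_delta", "resp_noise_sd", "broadband",
                          "emg_sd", "burst_gain", "nrem_onset", "odor_resp_step",
                          "mask_outside_sensor", "asymmetry", "animal_id",
                          "stimulus_label", "object_position", "arena_radius")

#' Compose a full synthetic session
#'
#' Runs the respiration, EEG/EMG and (for exploration conditions) tracking
#' generators on a shared clock, assembles a canonical four-channel
#' `signal_record` plus events, tracking and ground truth, and optionally
#' writes the native on-disk layout. For `condition = "sleep_odor"` the
#' session follows the sleep-trial design: the respiration sensor turns on
#' 10 s after NREM onset for one minute, the odor arrives 10 s after that
#' (NREM onset + 20 s), respiration steps up by `odor_resp_step` at odor
#' time, and the gap mask covers all samples outside the sensor window.
#'
#' @param config Named list; unknown keys are an error. Main keys:
#'   `condition`, `duration` (s), `fs`, `states` (data frame state/start/end
#'   or NULL for all-wake), `approach_plan`, `bout_increment` (Hz),
#'   `couplings` + `bout_coupling_delta` (see [coupling_spec()]),
#'   `nrem_onset` (s), `odor_resp_step` (Hz).
#' @param seed Global session seed.
#' @param out_dir Optional output directory for [write_session()].
#' @return List with `record`, `events`, `tracking`, `truth`, `manifest`.
#' @export
generate_session <- function(config = list(), seed = 1, out_dir = NULL) {
  bad <- setdiff(names(config), .SESSION_CONFIG_KEYS)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(list(
    condition = "open_arena", duration = 120, fs = 400, states = NULL,
    approach_plan = NULL, bout_increment = 5, couplings = NULL,
    bout_coupling_delta = NULL, resp_noise_sd = 0.02, broadband = 0.3,
    emg_sd = 1, burst_gain = 10, nrem_onset = 60, odor_resp_step = 2,
    mask_outside_sensor = TRUE, asymmetry = 0.4, animal_id = "synthetic_01",
    stimulus_label = "", object_position = c(12, 0), arena_radius = 25),
    config)
  fs <- cfg$fs
  dur <- cfg$duration

  sleep <- identical(cfg$condition, "sleep_odor")
  if (is.null(cfg$states)) {
    if (sleep) {
      on <- cfg$nrem_onset
      if (on + 70 > dur) stop("sleep session too short for the trial layout")
      cfg$states <- data.frame(state = c("wake", "NREM"),
                               start = c(0, on), end = c(on, dur))
    } else {
      cfg$states <- data.frame(state = "wake", start = 0, end = dur)
    }
  }
  schedule <- state_schedule(cfg$states$state, cfg$states$start,
                             cfg$states$end)

  tracking <- NULL
  events <- event_track()
  bouts <- NULL
  if (sleep) {
    on <- cfg$nrem_onset
    sensor_on <- on + 10
    odor_time <- sensor_on + 10
    events <- event_track(c("sensor_on", "odor_introduction"),
                          c(sensor_on, odor_time),
                          c(sensor_on + 60, NA))
    # the odor-evoked sniff step is injected through the bout mechanism
    bouts <- event_track("exploration_bout", odor_time,
                         min(odor_time + 20, dur))
    bout_inc <- cfg$odor_resp_step
  } else {
    if (!is.null(cfg$approach_plan)) {
      tb <- generate_tracking_and_bouts(cfg$arena_radius, cfg$object_position,
                                        cfg$approach_plan, 25, dur, seed)
      tracking <- tb$tracking
      events <- tb$events
      bouts <- tb$events
    }
    bout_inc <- cfg$bout_increment
  }

  resp <- generate_respiration(schedule, bouts = bouts, fs = fs, seed = seed,
                               bout_increment = bout_inc,
                               asymmetry = cfg$asymmetry,
                               noise_sd = cfg$resp_noise_sd)
  spec <- coupling_spec(cfg$couplings, cfg$bout_coupling_delta)
  movement <- if (!sleep && !is.null(bouts)) bouts else NULL
  ee <- generate_coupled_eeg_emg(resp$channel, spec, movement = movement,
                                 fs = fs, seed = seed, bouts = bouts,
                                 schedule = schedule,
                                 broadband = cfg$broadband,
                                 emg_sd = cfg$emg_sd,
                                 burst_gain = cfg$burst_gain)
  n <- length(resp$channel)
  gap <- rep(FALSE, n)
  if (sleep && cfg$mask_outside_sensor) {
    tt <- (0:(n - 1)) / fs
    gap <- !(tt >= cfg$nrem_onset + 10 & tt < cfg$nrem_onset + 70)
  }
  record <- signal_record(cbind(EEG1 = ee$eeg1, EEG2 = ee$eeg2,
                                EMG = ee$emg, Resp = resp$channel),
                          sample_rate = fs, gap_mask = gap)
  truth <- list(
    seed = seed,
    states = schedule$segments,
    state_params = schedule$params,
    bouts = if (!is.null(bouts)) as.data.frame(bouts)[c("start", "end")],
    bout_increment = if (!is.null(bouts)) bout_inc,
    inhalation_times = resp$truth$inhalation_times,
    coupling = ee$truth$bands,
    emg = ee$truth$emg,
    odor_time = if (sleep) cfg$nrem_onset + 20,
    sensor_window = if (sleep) c(cfg$nrem_onset + 10, cfg$nrem_onset + 70)
  )
  manifest <- session_manifest(cfg$animal_id, cfg$condition,
                               cfg$stimulus_label)
  session <- list(record = record, events = events, tracking = tracking,
                  truth = truth, manifest = manifest,
                  frequency = resp$truth$frequency)
  if (!is.null(out_dir)) {
    write_session(session, out_dir)
    data.table::fwrite(
      data.table::data.table(frequency = resp$truth$frequency),
      file.path(out_dir, "truth_frequency.csv"))
  }
  session
}
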