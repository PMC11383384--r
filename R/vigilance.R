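# Rule-based wake/NREM/REM scoring in 5-s epochs from EEG band power and
# EMG tone, plus sleep-odor trial bookkeeping.

.epoch_band_density <- function(x, fs, band) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(fft(x))^2 / n
  freqs <- (0:(n - 1)) * fs / n
  sel <- freqs >= band[1] & freqs < band[2] & freqs <= fs / 2
  mean(P[sel])
}

#' Score vigilance states in 5-s epochs
#'
#' Per epoch the scorer computes delta (1--4 Hz) power density, theta
#' (4--10 Hz) power density on the mean of the two EEG channels, and the
#' EMG RMS, then applies the rule: EMG above the tone threshold = wake;
#' otherwise delta above the delta threshold = NREM; otherwise theta/delta
#' ratio above the ratio threshold = REM; otherwise wake. Thresholds are
#' relative to session medians (EMG: `emg_factor` x median epoch RMS;
#' delta: `delta_factor` x median epoch delta power), so labels are
#' invariant to common positive rescaling of the channels.
#'
#' @param eeg1,eeg2 EEG channels (use `eeg2 = NULL` to score a single EEG).
#' @param emg EMG channel.
#' @param fs Sampling rate, Hz.
#' @param epoch Epoch length, s (5).
#' @param thresholds List with `emg_factor` (2), `delta_factor` (1.5),
#'   `ratio` (1); all must be positive.
#' @param smooth Apply 2-epoch median smoothing to the labels (off by
#'   default; raw 5-s epochs are scored).
#' @param start_time Time of the first sample, s.
#' @return Data frame of class `hypnogram` with `epoch_start` (s), `label`,
#'   `delta_power`, `theta_power`, `emg_rms`; attribute `qc_rem_to_nrem`
#'   counts physiologically unusual REM-to-NREM transitions (flagged, not
#'   enforced).
#' @export
score_states <- function(eeg1, eeg2 = NULL, emg, fs, epoch = 5,
                         thresholds = list(emg_factor = 2,
                                           delta_factor = 1.5, ratio = 1),
                         smooth = FALSE, start_time = 0) {
  th <- utils::modifyList(list(emg_factor = 2, delta_factor = 1.5, ratio = 1),
                          thresholds)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  eeg <- if (is.null(eeg2)) eeg1 else (eeg1 + eeg2) / 2
  nper <- round(epoch * fs)
  nep <- length(eeg) %/% nper
  if (nep < 1) stop("record shorter than one epoch")
  idx <- function(e) ((e - 1) * nper + 1):(e * nper)
  delta <- vapply(seq_len(nep), function(e)
    .epoch_band_density(eeg[idx(e)], fs, SCORING_BANDS$delta), numeric(1))
  theta <- vapply(seq_len(nep), function(e)
    .epoch_band_density(eeg[idx(e)], fs, SCORING_BANDS$theta), numeric(1))
  emg_rms <- vapply(seq_len(nep), function(e)
    sqrt(mean(emg[idx(e)]^2)), numeric(1))
  emg_thr <- th$emg_factor * median(emg_rms)
  delta_thr <- th$delta_factor * median(delta)
  label <- ifelse(emg_rms > emg_thr, "wake",
           ifelse(delta > delta_thr, "NREM",
           ifelse(theta / delta > th$ratio, "REM", "wake")))
  if (smooth && nep >= 3) {
    lv <- c(wake = 1, NREM = 2, REM = 3)
    num <- lv[label]
    sm <- num
    for (e in 2:(nep - 1)) sm[e] <- median(num[(e - 1):(e + 1)])
    label <- names(lv)[sm]
  }
  out <- data.frame(epoch_start = start_time + (seq_len(nep) - 1) * epoch,
                    label = label, delta_power = delta, theta_power = theta,
                    emg_rms = emg_rms)
  attr(out, "epoch") <- epoch
  attr(out, "qc_rem_to_nrem") <-
    sum(label[-length(label)] == "REM" & label[-1] == "NREM")
  class(out) <- c("hypnogram", "data.frame")
  out
}

#' State label at given times
#'
#' @param hypnogram A `hypnogram`.
#' @param t Times, s.
#' @return Character vector of labels (NA outside coverage).
#' @export
state_at <- function(hypnogram, t) {
  epoch <- attr(hypnogram, "epoch")
  if (is.null(epoch)) epoch <- 5
  i <- findInterval(t, hypnogram$epoch_start)
  lab <- rep(NA_character_, length(t))
  ok <- i >= 1 & t < hypnogram$epoch_start[pmin(i, nrow(hypnogram))] + epoch &
    i <= nrow(hypnogram)
  lab[ok] <- hypnogram$label[i[ok]]
  lab
}

#' Sleep-odor trial window layout
#'
#' The sensor turns on 10 s after NREM onset (for 1 min); the odor arrives
#' 10 s after that; the state-transition window is the following 20 s
#' (half-open). The 5-s comparison windows bracket the odor time.
#'
#' @param nrem_onset NREM onset, s.
#' @return List of class `sleep_trial_windows` with `nrem_onset`,
#'   `sensor_on`, `odor_time`, `transition_window`, `pre_window`,
#'   `post_window`.
#' @export
sleep_trial_windows <- function(nrem_onset) {
  sensor_on <- nrem_onset + 10
  odor_time <- sensor_on + 10
  structure(list(nrem_onset = nrem_onset, sensor_on = sensor_on,
                 odor_time = odor_time,
                 transition_window = c(odor_time, odor_time + 20),
                 pre_window = c(odor_time - 5, odor_time),
                 post_window = c(odor_time, odor_time + 5)),
            class = "sleep_trial_windows")
}

#' Sleep-odor trial outcomes
#'
#' Per trial: the first label change inside the 20-s transition window
#' determines the outcome (`to_wake`, `to_REM`), otherwise the animal
#' `remained_NREM`. Trials where the animal was not in NREM at odor time
#' are excluded (the placement itself woke the animal).
#'
#' @param hypnograms A `hypnogram` or list of them (one per trial).
#' @param windows A `sleep_trial_windows` or list of them.
#' @return List of class `sleep_trial_outcomes`: `outcome` per trial
#'   (NA = excluded), `proportions` over included trials, `n_excluded`.
#' @export
sleep_trial_outcomes <- function(hypnograms, windows) {
  if (inherits(hypnograms, "hypnogram")) hypnograms <- list(hypnograms)
  if (inherits(windows, "sleep_trial_windows")) windows <- list(windows)
  stopifnot(length(hypnograms) == length(windows))
  outcome <- vapply(seq_along(hypnograms), function(i) {
    h <- hypnograms[[i]]; w <- windows[[i]]
    epoch <- attr(h, "epoch"); if (is.null(epoch)) epoch <- 5
    if (max(h$epoch_start) + epoch < w$transition_window[2])
      stop("hypnogram does not cover the transition window")
    if (!identical(state_at(h, w$odor_time), "NREM")) return(NA_character_)
    sel <- h$epoch_start + epoch > w$transition_window[1] &
      h$epoch_start < w$transition_window[2]
    lab <- h$label[sel]
    chg <- which(lab != "NREM")
    if (length(chg) == 0) "remained_NREM"
    else if (lab[chg[1]] == "wake") "to_wake" else "to_REM"
  }, character(1))
  inc <- outcome[!is.na(outcome)]
  props <- if (length(inc))
    table(factor(inc, c("remained_NREM", "to_wake", "to_REM"))) / length(inc)
  else NULL
  structure(list(outcome = outcome,
                 proportions = props,
                 n_excluded = sum(is.na(outcome))),
            class = "sleep_trial_outcomes")
}

#' Paired pre/post odor comparison
#'
#' Per trial, means of a measured series over the 5-s windows before and
#' after odor time; across trials, a paired t test. With fewer than two
#' trials the means are reported and the test omitted. Identical pre and
#' post values give p = 1.
#'
#' @param series A data frame `time`/`value` or list of them (per trial).
#' @param windows A `sleep_trial_windows` or list of them.
#' @return List of class `windowed_comparison`: `pre_means`, `post_means`,
#'   `mean_difference`, `t_statistic`, `p_value`.
#' @export
windowed_comparison <- function(series, windows) {
  if (is.data.frame(series)) series <- list(series)
  if (inherits(windows, "sleep_trial_windows")) windows <- list(windows)
  stopifnot(length(series) == length(windows))
  wmean <- function(s, w)
    mean(s$value[s$time >= w[1] & s$time < w[2]], na.rm = TRUE)
  pre <- vapply(seq_along(series), function(i)
    wmean(series[[i]], windows[[i]]$pre_window), numeric(1))
  post <- vapply(seq_along(series), function(i)
    wmean(series[[i]], windows[[i]]$post_window), numeric(1))
  d <- post - pre
  tstat <- NA_real_; pval <- NA_real_
  if (length(d) >= 2) {
    if (sd(d) < 1e-12) {
      tstat <- 0; pval <- 1
    } else {
      tt <- t.test(post, pre, paired = TRUE)
      tstat <- unname(tt$statistic); pval <- tt$p.value
    }
  }
  structure(list(pre_means = pre, post_means = post,
                 mean_difference = mean(d), t_statistic = tstat,
                 p_value = pval),
            class = "windowed_comparison")
}
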