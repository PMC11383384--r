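# Respiration analyses: rolling dominant-frequency estimation via
# autocorrelation, inhalation-peak (trough) detection, sensor-agreement
# metrics, bout-aligned frequency trials and intersniff statistics.

# per-lag Pearson-normalized autocorrelation of a window: the correlation
# between the two overlapping segments at each lag. Unlike the plain sample
# autocorrelation its peak sits exactly at the period of a pure tone (the
# two segments are then identical), free of the finite-window edge term
# that drags the conventional estimate off the true lag.
.pearson_acf <- function(x, max_lag) {
  n <- length(x)
  m <- stats::nextn(2 * n, 2)
  X <- fft(c(x, rep(0, m - n)))
  C <- Re(fft(X * Conj(X), inverse = TRUE))[1:(max_lag + 1)] / m
  cs <- cumsum(x); cq <- cumsum(x^2)
  L <- 0:max_lag
  nm <- n - L
  S1 <- cs[nm]
  S2 <- cs[n] - c(0, cs[L[-1]])
  Q1 <- cq[nm]
  Q2 <- cq[n] - c(0, cq[L[-1]])
  num <- C - S1 * S2 / nm
  den <- sqrt(pmax(Q1 - S1^2 / nm, 0) * pmax(Q2 - S2^2 / nm, 0))
  ifelse(den > 1e-12, num / den, 0)
}

# dominant frequency of one standardized, detrended window: first local
# maximum of the autocorrelation after its first zero crossing, subject to
# a lag floor (caps detectable frequency) and a minimum autocorrelation
# value; the peak lag is refined by parabolic interpolation.
.window_frequency <- function(x, fs, min_freq, max_freq, min_acf) {
  if (sd(x) < .Machine$double.eps) return(NA_real_)
  n <- length(x)
  x <- x - mean(x)
  tt <- seq_len(n)
  x <- stats::lm.fit(cbind(1, tt), x)$residuals
  x <- x / sd(x)
  max_lag <- min(n - 10L, as.integer(ceiling(fs / min_freq)))
  a <- .pearson_acf(x, max_lag)
  zc <- which(a <= 0)[1]
  if (is.na(zc)) return(NA_real_)
  floor_lag <- as.integer(ceiling(fs / max_freq))
  st <- max(zc, floor_lag + 1L)          # index in a = lag + 1
  if (st + 1 > length(a)) return(NA_real_)
  seg <- a[st:length(a)]
  m <- length(seg)
  if (m < 3) return(NA_real_)
  pks <- which(seg[2:(m - 1)] > seg[1:(m - 2)] &
               seg[2:(m - 1)] >= seg[3:m]) + 1L
  # a qualifying peak must clear the fixed floor and be significant for
  # its overlap (guards against spurious long-lag correlations)
  overlap <- n - (st + pks - 2L)
  pks <- pks[seg[pks] >= pmax(min_acf, 4 / sqrt(overlap))]
  if (length(pks) == 0) return(NA_real_)
  i <- st + pks[1] - 1L                  # index in a of the peak
  y1 <- a[i - 1]; y2 <- a[i]; y3 <- a[i + 1]
  denom <- y1 - 2 * y2 + y3
  offset <- if (abs(denom) > .Machine$double.eps) (y1 - y3) / (2 * denom) else 0
  offset <- max(min(offset, 0.5), -0.5)
  lag <- (i - 1) + offset
  fs / lag
}

#' Rolling dominant respiration frequency
#'
#' For each 1-s window (shifted by 50 ms): standardize and linearly detrend,
#' compute the autocorrelation (with per-lag Pearson normalization, so the
#' peak of a periodic window sits exactly at its period), locate the first
#' local maximum after the first zero crossing with lag >= 1/max_freq and
#' autocorrelation >= 0.2, refine the peak lag by parabolic interpolation,
#' and report its reciprocal as the dominant frequency. Windows with no
#' qualifying peak (or zero variance) yield a missing value.
#'
#' @param x Respiration signal.
#' @param fs Sampling rate, Hz.
#' @param window Window length, s (1.0).
#' @param shift Window shift, s (0.05).
#' @param min_freq,max_freq Detectable frequency range, Hz (1 and 15).
#' @param min_acf Minimum qualifying autocorrelation peak value (0.2).
#' @param start_time Time of the first sample, s.
#' @return Data frame of class `resp_frequency_series` with
#'   `window_center` (s) and `frequency` (Hz, NA where undetermined);
#'   attributes `window`, `shift`.
#' @export
estimate_resp_frequency <- function(x, fs, window = 1.0, shift = 0.05,
                                    min_freq = 1, max_freq = 15,
                                    min_acf = 0.2, start_time = 0) {
  nwin <- round(window * fs)
  nshift <- round(shift * fs)
  if (length(x) < nwin) stop("signal shorter than one window")
  starts <- seq(1L, length(x) - nwin + 1L, by = nshift)
  freq <- vapply(starts, function(s) {
    .window_frequency(x[s:(s + nwin - 1L)], fs, min_freq, max_freq, min_acf)
  }, numeric(1))
  n_flat <- sum(vapply(starts, function(s)
    sd(x[s:(s + nwin - 1L)]) < .Machine$double.eps, logical(1)))
  if (n_flat > 0)
    warning(sprintf("%d constant (zero-variance) windows set to missing",
                    n_flat))
  out <- data.frame(window_center = start_time + (starts - 1) / fs + window / 2,
                    frequency = freq)
  attr(out, "window") <- window
  attr(out, "shift") <- shift
  class(out) <- c("resp_frequency_series", "data.frame")
  out
}

#' Detect inhalation peaks (sniff-cycle troughs)
#'
#' The signal is band-pass filtered (zero phase) to the sniffing band, and
#' local minima with depth-below-zero prominence of at least
#' `prominence_frac` of the median trough depth and spacing of at least
#' 1/max_freq are taken as inhalation peaks. When `require_periodicity` is
#' TRUE (default) troughs are only kept inside windows where the rolling
#' autocorrelation estimator finds a dominant frequency, which suppresses
#' spurious troughs in non-oscillatory stretches.
#'
#' @param x Respiration signal.
#' @param fs Sampling rate, Hz.
#' @param min_freq,max_freq Sniffing band, Hz (1 and 15).
#' @param prominence_frac Fraction of the median trough depth (0.25).
#' @param require_periodicity Gate troughs on rolling-frequency coverage.
#' @param start_time Time of the first sample, s.
#' @return Object of class `inhalation_peaks`: list with `peak_times`
#'   (strictly increasing, s) and the detection parameters.
#' @export
detect_inhalation_peaks <- function(x, fs, min_freq = 1, max_freq = 15,
                                    prominence_frac = 0.25,
                                    require_periodicity = TRUE,
                                    start_time = 0) {
  if (min_freq <= 0 || max_freq >= fs / 2)
    stop("frequency bounds must lie inside (0, fs/2)")
  if (sd(x) < .Machine$double.eps)
    return(structure(list(peak_times = numeric(), fs = fs),
                     class = "inhalation_peaks"))
  y <- bandpass_filter(x, fs, min_freq, max_freq)
  n <- length(y)
  cand <- which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
  cand <- cand[y[cand] < 0]
  if (length(cand) == 0)
    return(structure(list(peak_times = numeric(), fs = fs),
                     class = "inhalation_peaks"))
  depth <- -y[cand]
  keep <- depth >= prominence_frac * median(depth)
  cand <- cand[keep]
  minsp <- as.integer(round(fs / max_freq))
  out <- integer(0); last <- -minsp
  for (i in cand) {
    if (i - last >= minsp) { out <- c(out, i); last <- i }
  }
  times <- start_time + (out - 1L) / fs
  if (require_periodicity && length(x) >= fs) {
    fr <- suppressWarnings(estimate_resp_frequency(x, fs,
                                                   min_freq = min_freq,
                                                   max_freq = max_freq,
                                                   start_time = start_time))
    ok <- !is.na(fr$frequency)
    if (!any(ok)) {
      times <- numeric()
    } else {
      centers <- fr$window_center[ok]
      half <- attr(fr, "window") / 2
      covered <- vapply(times, function(tm)
        any(abs(tm - centers) <= half), logical(1))
      times <- times[covered]
    }
  }
  structure(list(peak_times = times, fs = fs,
                 params = list(min_freq = min_freq, max_freq = max_freq,
                               prominence_frac = prominence_frac)),
            class = "inhalation_peaks")
}

#' Relative error between thoracic and flow frequency series
#'
#' Per window: (f_thoracic - f_flow) / f_flow; per trial the windows are
#' averaged; the population mean and SD are taken across trials. Windows
#' where the flow frequency is missing or zero are excluded and counted.
#'
#' @param freq_thoracic,freq_flow A `resp_frequency_series` each, or lists
#'   of them (one element per trial). Series within a trial must share the
#'   window grid.
#' @return List of class `relative_error_summary`: `per_trial_mean_error`,
#'   `population_mean`, `population_sd`, `n_excluded_windows`.
#' @export
relative_error <- function(freq_thoracic, freq_flow) {
  if (inherits(freq_thoracic, "resp_frequency_series"))
    freq_thoracic <- list(freq_thoracic)
  if (inherits(freq_flow, "resp_frequency_series"))
    freq_flow <- list(freq_flow)
  stopifnot(length(freq_thoracic) == length(freq_flow))
  excluded <- 0L
  per_trial <- vapply(seq_along(freq_thoracic), function(i) {
    th <- freq_thoracic[[i]]; fl <- freq_flow[[i]]
    if (nrow(th) != nrow(fl) ||
        max(abs(th$window_center - fl$window_center)) > 1e-9)
      stop("series do not share a window grid")
    ok <- !is.na(fl$frequency) & fl$frequency != 0 & !is.na(th$frequency)
    excluded <<- excluded + sum(!ok)
    mean((th$frequency[ok] - fl$frequency[ok]) / fl$frequency[ok])
  }, numeric(1))
  structure(list(per_trial_mean_error = per_trial,
                 population_mean = mean(per_trial),
                 population_sd = if (length(per_trial) > 1) sd(per_trial) else 0,
                 n_excluded_windows = excluded),
            class = "relative_error_summary")
}

#' Inhalation-peak lag between flow and thoracic sensors
#'
#' Nearest-neighbour pairing of flow peaks with thoracic peaks within half
#' the median flow inter-peak interval; lag = flow time - thoracic time, so
#' lags are negative when flow precedes thoracic pressure. Unpaired peaks
#' are dropped and counted.
#'
#' @param flow_peaks,thoracic_peaks `inhalation_peaks` objects (nonempty).
#' @return List of class `peak_lag_summary` with `lags`, `mean_lag`,
#'   `sd_lag`, `n_pairs`, `n_unpaired_flow`, `n_unpaired_thoracic`.
#' @export
peak_lag <- function(flow_peaks, thoracic_peaks) {
  fl <- flow_peaks$peak_times
  th <- thoracic_peaks$peak_times
  if (length(fl) == 0 || length(th) == 0)
    stop("both peak trains must be nonempty")
  tol <- if (length(fl) > 1) median(diff(fl)) / 2 else Inf
  used <- rep(FALSE, length(th))
  lags <- rep(NA_real_, length(fl))
  for (i in seq_along(fl)) {
    d <- abs(th - fl[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol) {
      lags[i] <- fl[i] - th[j]
      used[j] <- TRUE
    }
  }
  ok <- !is.na(lags)
  if (!any(ok)) stop("trains not concurrent: no pairs within tolerance")
  structure(list(lags = lags[ok], mean_lag = mean(lags[ok]),
                 sd_lag = if (sum(ok) > 1) sd(lags[ok]) else 0,
                 n_pairs = sum(ok),
                 n_unpaired_flow = sum(!ok),
                 n_unpaired_thoracic = sum(!used)),
            class = "peak_lag_summary")
}

#' Bout-aligned respiration-frequency trials
#'
#' One trial per exploration bout: the 3 s preceding and following the bout
#' are included, trials are aligned to bout start (t = 0), the baseline is
#' the mean frequency over the first 500 ms of the trial and the
#' exploration frequency the mean over the first 1 s of the bout. Bouts
#' with less than `pre` seconds of preceding recording are discarded, as
#' are trials whose baseline has more than 50% missing windows (counted).
#'
#' @param freq A `resp_frequency_series`.
#' @param bouts An `event_track` of exploration bouts (sorted).
#' @param pre,post Seconds included before bout start / after bout end.
#' @return Object of class `trial_aligned_frequency`: list with `time`
#'   (common grid relative to bout start), `traces` (trials x time),
#'   `delta_traces` (baseline-subtracted), `baseline_frequency`,
#'   `exploration_frequency`, `delta_frequency`, `cue_class`,
#'   `n_discarded_short`, `n_discarded_missing`.
#' @export
extract_bout_trials <- function(freq, bouts, pre = 3, post = 3) {
  shift <- attr(freq, "shift")
  t0 <- min(freq$window_center)
  n_short <- 0L; n_missing <- 0L
  keep <- list()
  for (i in seq_len(nrow(bouts))) {
    bs <- bouts$start[i]; be <- bouts$end[i]
    if (bs - pre < t0 - shift / 2) { n_short <- n_short + 1L; next }
    sel <- freq$window_center >= bs - pre & freq$window_center < be + post
    rel <- freq$window_center[sel] - bs
    f <- freq$frequency[sel]
    base_sel <- rel >= -pre & rel < -pre + 0.5
    if (mean(is.na(f[base_sel])) > 0.5) { n_missing <- n_missing + 1L; next }
    baseline <- mean(f[base_sel], na.rm = TRUE)
    expl_sel <- rel >= 0 & rel < 1
    exploration <- mean(f[expl_sel], na.rm = TRUE)
    keep[[length(keep) + 1]] <- list(rel = rel, f = f, baseline = baseline,
                                     exploration = exploration,
                                     cue = if ("cue_class" %in% names(bouts))
                                       bouts$cue_class[i] else NA_character_)
  }
  if (length(keep) == 0) {
    warning("no surviving bouts")
    return(structure(list(time = numeric(), traces = NULL,
                          delta_traces = NULL,
                          baseline_frequency = numeric(),
                          exploration_frequency = numeric(),
                          delta_frequency = numeric(),
                          cue_class = character(),
                          n_discarded_short = n_short,
                          n_discarded_missing = n_missing),
                     class = "trial_aligned_frequency"))
  }
  # common grid: from -pre to the shortest trial end, on the shift grid
  tmax <- min(vapply(keep, function(k) max(k$rel), numeric(1)))
  grid <- seq(-pre, tmax, by = shift)
  traces <- t(vapply(keep, function(k) {
    approx(k$rel, k$f, xout = grid)$y
  }, numeric(length(grid))))
  baseline <- vapply(keep, `[[`, numeric(1), "baseline")
  structure(list(time = grid, traces = traces,
                 delta_traces = traces - baseline,
                 baseline_frequency = baseline,
                 exploration_frequency = vapply(keep, `[[`, numeric(1),
                                                "exploration"),
                 delta_frequency = vapply(keep, `[[`, numeric(1),
                                          "exploration") - baseline,
                 cue_class = vapply(keep, `[[`, character(1), "cue"),
                 n_discarded_short = n_short,
                 n_discarded_missing = n_missing),
            class = "trial_aligned_frequency")
}

#' Intersniff-interval statistics per vigilance state
#'
#' Intervals between consecutive inhalation peaks, assigned to the state of
#' the 5-s epoch containing the earlier peak. The per-state mean frequency
#' is the reciprocal of the mean interval. States with fewer than two peaks
#' are omitted with a note.
#'
#' @param peaks An `inhalation_peaks` object.
#' @param hypnogram A `hypnogram` (see [score_states()]) covering the peaks.
#' @return List of class `intersniff_distribution`: per-state `intervals`
#'   (s), `mean_frequency` (Hz), `omitted_states`.
#' @export
intersniff_stats <- function(peaks, hypnogram) {
  pt <- peaks$peak_times
  if (length(pt) < 2) stop("need at least two peaks")
  iv <- diff(pt)
  st <- state_at(hypnogram, pt[-length(pt)])
  intervals <- split(iv, st)
  omitted <- character()
  for (s in unique(hypnogram$label)) {
    if (is.null(intervals[[s]]) || length(intervals[[s]]) < 1) {
      omitted <- c(omitted, s)
      intervals[[s]] <- NULL
    }
  }
  mean_freq <- vapply(intervals, function(v) 1 / mean(v), numeric(1))
  structure(list(intervals = intervals, mean_frequency = mean_freq,
                 omitted_states = omitted),
            class = "intersniff_distribution")
}
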