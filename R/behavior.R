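# Behavior: velocity from tracking, exploration-bout detection, EMG-based
# movement classification, and the respiration-vs-running-speed cross-check.

#' Instantaneous running velocity
#'
#' Centre-point displacement between consecutive frames times the frame
#' rate (the centre point avoids head-bobbing inflating the speed). The
#' first frame copies the second.
#'
#' @param trace A `tracking_trace` with at least two frames.
#' @return Data frame of class `velocity_series` with `frame_time` (s) and
#'   `speed` (cm/s).
#' @export
compute_velocity <- function(trace) {
  n <- length(trace$frame_times)
  if (n < 2) stop("need at least two frames")
  if (any(diff(trace$frame_times) <= 0))
    stop("frame times must be strictly increasing")
  d <- sqrt(rowSums((trace$center[-1, , drop = FALSE] -
                     trace$center[-n, , drop = FALSE])^2))
  sp <- d / diff(trace$frame_times)
  sp <- c(sp[1], sp)
  out <- data.frame(frame_time = trace$frame_times, speed = sp)
  class(out) <- c("velocity_series", "data.frame")
  out
}

#' Detect exploration bouts from nose position
#'
#' A bout starts at the first frame where the nose is within `radius` cm of
#' the object centroid (inclusive boundary: distance exactly equal to the
#' radius counts as inside) and ends at the next frame where it moves out;
#' consecutive inside frames form one bout.
#'
#' @param trace A `tracking_trace`.
#' @param object_position Object centroid, cm.
#' @param radius Perimeter radius, cm (2).
#' @param cue_class Optional cue class recorded on each bout.
#' @return An `event_track` of `exploration_bout` events (possibly empty).
#' @export
detect_exploration_bouts <- function(trace, object_position, radius = 2,
                                     cue_class = NA_character_) {
  d <- sqrt((trace$nose[, 1] - object_position[1])^2 +
            (trace$nose[, 2] - object_position[2])^2)
  inside <- d <= radius
  if (!any(inside)) return(event_track())
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ft <- trace$frame_times
  dt <- 1 / trace$frame_rate
  bs <- ft[starts[r$values]]
  idx_end <- ends[r$values]
  # end = the next frame at which the nose is outside; if the run touches
  # the end of the trace, close the bout one frame step after the last frame
  be <- ifelse(idx_end < length(ft), ft[idx_end + 1], ft[idx_end] + dt)
  event_track(rep("exploration_bout", length(bs)), bs, be,
              rep(cue_class, length(bs)))
}

#' Classify movement from EMG root-mean-square
#'
#' RMS over sliding 2-s bins (step 0.5 s); a bin is "moving" when its RMS
#' exceeds `threshold_fraction` of the session-maximum bin RMS. The
#' threshold is relative, so classification is invariant to rescaling the
#' EMG channel.
#'
#' @param emg EMG signal.
#' @param fs Sampling rate, Hz.
#' @param bin Bin length, s (2).
#' @param step Bin step, s (0.5).
#' @param threshold_fraction Fraction of the maximum bin RMS, in
#'   `[0.10, 0.20]`.
#' @param start_time Time of the first sample, s.
#' @return Data frame of class `movement_track` with `bin_center` (s),
#'   `emg_rms`, `moving`; threshold recorded as an attribute.
#' @export
classify_movement <- function(emg, fs, bin = 2, step = 0.5,
                              threshold_fraction = 0.15, start_time = 0) {
  if (threshold_fraction < 0.10 || threshold_fraction > 0.20)
    stop("threshold_fraction must lie in [0.10, 0.20]")
  nbin <- round(bin * fs)
  nstep <- round(step * fs)
  if (length(emg) < nbin) stop("record shorter than one bin")
  starts <- seq(1L, length(emg) - nbin + 1L, by = nstep)
  rms <- vapply(starts, function(s)
    sqrt(mean(emg[s:(s + nbin - 1L)]^2)), numeric(1))
  thr <- threshold_fraction * max(rms)
  out <- data.frame(bin_center = start_time + (starts - 1) / fs + bin / 2,
                    emg_rms = rms, moving = rms > thr)
  attr(out, "threshold") <- thr
  attr(out, "threshold_fraction") <- threshold_fraction
  class(out) <- c("movement_track", "data.frame")
  out
}

#' Respiration frequency vs running velocity
#'
#' Resamples the velocity onto the frequency window centres and reports the
#' mean velocity inside two respiration-frequency bands (1--5 and 9--13 Hz
#' by default), the mean frequency inside two velocity bands (1--10 and
#' 35--45 cm/s), the Pearson correlation over all windows, and two-sample
#' t comparisons between the band pairs. Empty bands are omitted with a
#' note.
#'
#' @param freq A `resp_frequency_series`.
#' @param vel A `velocity_series` overlapping it in time.
#' @param freq_bands,vel_bands Lists of `c(lo, hi)` band edges.
#' @return List of class `freq_velocity_crosstab`.
#' @export
freq_velocity_crosstab <- function(freq, vel,
                                   freq_bands = list(c(1, 5), c(9, 13)),
                                   vel_bands = list(c(1, 10), c(35, 45))) {
  v <- approx(vel$frame_time, vel$speed, xout = freq$window_center)$y
  ok <- !is.na(freq$frequency) & !is.na(v)
  f <- freq$frequency[ok]; v <- v[ok]
  if (length(f) < 3) stop("series do not overlap")
  note <- character()
  band_stat <- function(values, by, bands, what) {
    lapply(bands, function(b) {
      sel <- by >= b[1] & by <= b[2]
      if (!any(sel)) {
        note <<- c(note, sprintf("%s band [%g, %g] empty", what, b[1], b[2]))
        return(list(band = b, n = 0L, mean = NA_real_, values = numeric()))
      }
      list(band = b, n = sum(sel), mean = mean(values[sel]),
           values = values[sel])
    })
  }
  vel_by_freq <- band_stat(v, f, freq_bands, "frequency")
  freq_by_vel <- band_stat(f, v, vel_bands, "velocity")
  cmp <- function(pair) {
    if (pair[[1]]$n > 1 && pair[[2]]$n > 1)
      t.test(pair[[1]]$values, pair[[2]]$values)$p.value
    else NA_real_
  }
  structure(list(
    vel_by_freq_band = vel_by_freq,
    freq_by_vel_band = freq_by_vel,
    velocity_comparison_p = cmp(vel_by_freq),
    frequency_comparison_p = cmp(freq_by_vel),
    correlation = stats::cor(f, v),
    n_windows = length(f),
    notes = note),
    class = "freq_velocity_crosstab")
}
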