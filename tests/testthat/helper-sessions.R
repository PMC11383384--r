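# shared builders for small synthetic fixtures, constructed in code

canonical_channels <- c("EEG1", "EEG2", "EMG", "Resp")

make_record <- function(samples, fs = 400, gap_mask = NULL) {
  colnames(samples) <- canonical_channels[seq_len(ncol(samples))]
  signal_record(samples, sample_rate = fs, gap_mask = gap_mask)
}

white_record <- function(seconds, fs = 400, seed = 1) {
  set.seed(seed)
  make_record(matrix(rnorm(4 * seconds * fs), ncol = 4), fs = fs)
}

# a resp_frequency_series built directly from values on the standard grid
make_freq_series <- function(values, shift = 0.05, start = 0.5) {
  out <- data.frame(window_center = start + (seq_along(values) - 1) * shift,
                    frequency = values)
  attr(out, "window") <- 1
  attr(out, "shift") <- shift
  class(out) <- c("resp_frequency_series", "data.frame")
  out
}

make_hypnogram <- function(labels, epoch = 5, start = 0) {
  out <- data.frame(epoch_start = start + (seq_along(labels) - 1) * epoch,
                    label = labels,
                    delta_power = NA_real_, theta_power = NA_real_,
                    emg_rms = NA_real_)
  attr(out, "epoch") <- epoch
  class(out) <- c("hypnogram", "data.frame")
  out
}

make_peaks <- function(times, fs = 400) {
  structure(list(peak_times = times, fs = fs), class = "inhalation_peaks")
}

# event starts snapped to a band's epoch grid, so lag-0 epochs sit fully
# inside the modulated interval
snapped_events <- function(n, spacing, band, first = 20) {
  ep <- epoch_length_for_band(band)
  starts <- ep * round((first + (0:(n - 1)) * spacing) / ep)
  event_track(rep("exploration_bout", n), starts, starts + 2 * ep)
}
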