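#' @importFrom stats approx coef lm median residuals rnorm runif sd t.test
#'   acf fft mvfft nextn p.adjust quantile var predict
#' @importFrom utils head tail
NULL

CANONICAL_CHANNELS <- c("EEG1", "EEG2", "EMG", "Resp")
CONDITIONS <- c("open_arena", "novel_object", "novel_odor", "food", "sleep_odor")

#' Synchronized multichannel signal record
#'
#' Container for the four physiology channels (EEG1, EEG2, EMG, Resp)
#' sampled on a common clock. `gap_mask` is TRUE where the respiration
#' telemetry was off; masked samples are excluded from all downstream
#' epoching (see [valid_segments()]).
#'
#' @param samples Numeric matrix, samples x channels, or a named list of
#'   equal-length numeric vectors.
#' @param channel_names Channel labels; defaults to the matrix/list names.
#' @param sample_rate Sampling rate in Hz (canonical 400).
#' @param start_time Record start, seconds.
#' @param gap_mask Logical vector, one entry per sample; TRUE = no Resp
#'   telemetry. Defaults to all-FALSE.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, channel_names = NULL, sample_rate = 400,
                          start_time = 0, gap_mask = NULL) {
  if (is.list(samples) && !is.data.frame(samples)) {
    if (is.null(channel_names)) channel_names <- names(samples)
    lens <- lengths(samples)
    if (length(unique(lens)) != 1)
      stop("all channels must have equal length")
    samples <- do.call(cbind, samples)
  }
  samples <- as.matrix(samples)
  if (is.null(channel_names)) channel_names <- colnames(samples)
  if (is.null(channel_names))
    stop("channel_names required")
  stopifnot(length(channel_names) == ncol(samples))
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (is.null(gap_mask)) gap_mask <- rep(FALSE, nrow(samples))
  if (length(gap_mask) != nrow(samples))
    stop("gap_mask length must equal sample length")
  colnames(samples) <- channel_names
  structure(list(samples = samples, channel_names = channel_names,
                 sample_rate = sample_rate, start_time = start_time,
                 gap_mask = as.logical(gap_mask)),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channels [%s], %d samples @ %g Hz (%.1f s)\n",
              length(x$channel_names), paste(x$channel_names, collapse = ", "),
              nrow(x$samples), x$sample_rate,
              nrow(x$samples) / x$sample_rate))
  ngap <- sum(x$gap_mask)
  if (ngap > 0)
    cat(sprintf("  gap mask: %d samples (%.1f s) without Resp telemetry\n",
                ngap, ngap / x$sample_rate))
  invisible(x)
}

#' Extract one channel of a signal record
#' @param record A `signal_record`.
#' @param channel Channel name.
#' @return Numeric vector.
#' @export
channel <- function(record, channel) {
  if (!channel %in% record$channel_names)
    stop(sprintf("channel %s missing", channel))
  record$samples[, channel]
}

#' Behavioral / stimulus event track
#'
#' @param kind Event kinds, each one of `exploration_bout`,
#'   `odor_introduction`, `sensor_on`.
#' @param start,end Event boundaries in seconds (half-open, `[start, end)`);
#'   `end` may be NA for point events.
#' @param cue_class Optional cue class (`object`, `odor`, `food`) or NA.
#' @return A data.frame of class `event_track`, sorted by start.
#' @export
event_track <- function(kind = character(), start = numeric(),
                        end = rep(NA_real_, length(start)),
                        cue_class = rep(NA_character_, length(start))) {
  ok <- kind %in% c("exploration_bout", "odor_introduction", "sensor_on")
  if (!all(ok)) stop("unknown event kind: ", paste(kind[!ok], collapse = ", "))
  if (any(!is.na(end) & end <= start))
    stop("event end must exceed start")
  df <- data.frame(kind = kind, start = start, end = end,
                   cue_class = cue_class, stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_track", "data.frame")
  df
}

#' Video tracking trace
#'
#' Nose / center / tail planar coordinates (cm) per video frame, with frame
#' times on the signal clock (from TTL alignment).
#'
#' @param frame_times Strictly increasing frame times, seconds.
#' @param nose,center,tail Two-column matrices of coordinates in cm.
#' @param frame_rate Nominal frame rate, Hz (25).
#' @return An object of class `tracking_trace`.
#' @export
tracking_trace <- function(frame_times, nose, center = nose, tail = nose,
                           frame_rate = 25) {
  nose <- as.matrix(nose); center <- as.matrix(center); tail <- as.matrix(tail)
  n <- length(frame_times)
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  if (nrow(nose) != n || nrow(center) != n || nrow(tail) != n)
    stop("coordinate arrays must match frame_times length")
  structure(list(frame_times = frame_times, nose = nose, center = center,
                 tail = tail, frame_rate = frame_rate),
            class = "tracking_trace")
}

#' Session manifest
#'
#' @param animal_id Nonempty animal label.
#' @param condition One of `open_arena`, `novel_object`, `novel_odor`,
#'   `food`, `sleep_odor`.
#' @param stimulus_label Free-text stimulus description.
#' @param path Session directory (native CSV + JSON layout) or an EDF file.
#' @param channel_map Named character vector mapping canonical channel names
#'   to on-disk channel labels; defaults to identity.
#' @return An object of class `session_manifest`.
#' @export
session_manifest <- function(animal_id, condition, stimulus_label = "",
                             path = NULL,
                             channel_map = setNames(CANONICAL_CHANNELS,
                                                    CANONICAL_CHANNELS)) {
  if (!nzchar(animal_id)) stop("animal_id must be nonempty")
  condition <- match.arg(condition, CONDITIONS)
  structure(list(animal_id = animal_id, condition = condition,
                 stimulus_label = stimulus_label, path = path,
                 channel_map = channel_map),
            class = "session_manifest")
}

#' Contiguous unmasked segments of a record
#'
#' Enumerates maximal runs of samples where the gap mask is FALSE, as
#' half-open intervals. Segments shorter than `min_duration` are dropped
#' (gap handling: short fragments cannot host a full locally-stationary
#' epoch and are never padded).
#'
#' @param record A `signal_record`.
#' @param min_duration Minimum segment duration in seconds.
#' @return Data frame with columns `start_sample`, `end_sample` (1-based,
#'   half-open on the sample grid) and `start_time`, `end_time` (seconds).
#' @export
valid_segments <- function(record, min_duration = 0) {
  m <- !record$gap_mask
  if (!any(m)) stop("no valid data: entire record is masked")
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  seg <- data.frame(start_sample = starts[keep], end_sample = ends[keep] + 1L)
  fs <- record$sample_rate
  seg$start_time <- record$start_time + (seg$start_sample - 1) / fs
  seg$end_time <- record$start_time + (seg$end_sample - 1) / fs
  seg <- seg[seg$end_time - seg$start_time >= min_duration, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Apply the telemetry gap mask
#'
#' Validates the mask and attaches the enumerated valid segments to the
#' record. Downstream epoching only ever draws epochs from these segments,
#' so no epoch straddles a masked interval.
#'
#' @param record A `signal_record`.
#' @return The record with a `segments` element.
#' @export
apply_gap_mask <- function(record) {
  record$segments <- valid_segments(record)
  record
}

#' Re-time video frames onto the signal clock
#'
#' Replaces the trace's frame times with the TTL pulse times recorded on
#' the acquisition clock (one TTL per frame). TTL times are treated as
#' authoritative.
#'
#' @param trace A `tracking_trace`.
#' @param ttl_times TTL pulse times, seconds, one per frame.
#' @return The trace with `frame_times = ttl_times`.
#' @export
align_video_frames <- function(trace, ttl_times) {
  nf <- length(trace$frame_times); nt <- length(ttl_times)
  if (abs(nf - nt) > 1)
    stop(sprintf("TTL/frame count mismatch: %d frames vs %d TTL pulses", nf, nt))
  n <- min(nf, nt)
  tracking_trace(ttl_times[seq_len(n)],
                 trace$nose[seq_len(n), , drop = FALSE],
                 trace$center[seq_len(n), , drop = FALSE],
                 trace$tail[seq_len(n), , drop = FALSE],
                 trace$frame_rate)
}

# ---- native on-disk format: CSV channel table + JSON sidecar -------------

#' Write a session to disk
#'
#' Native layout: `channels.csv` (one column per channel plus `gap_mask`),
#' `session.json` (manifest, sample rate, events, ground truth if present)
#' and optionally `tracking.csv`. Written deterministically: the same
#' session yields byte-identical files.
#'
#' @param session A list with elements `record` (signal_record), and
#'   optionally `events` (event_track), `tracking` (tracking_trace),
#'   `manifest` (session_manifest), `truth` (list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- session$record
  # 17 significant digits so doubles survive the text round trip exactly
  dt <- data.table::as.data.table(
    apply(rec$samples, 2, sprintf, fmt = "%.17g"))
  dt$gap_mask <- as.integer(rec$gap_mask)
  data.table::fwrite(dt, file.path(dir, "channels.csv"))
  side <- list(
    sample_rate = rec$sample_rate,
    start_time = rec$start_time,
    channel_names = rec$channel_names,
    manifest = if (!is.null(session$manifest)) unclass(session$manifest),
    events = if (!is.null(session$events)) as.data.frame(session$events),
    truth = session$truth
  )
  writeLines(jsonlite::toJSON(side, digits = NA, auto_unbox = TRUE,
                              null = "null", pretty = TRUE),
             file.path(dir, "session.json"))
  if (!is.null(session$tracking)) {
    tr <- session$tracking
    data.table::fwrite(data.table::data.table(
      frame_time = tr$frame_times,
      nose_x = tr$nose[, 1], nose_y = tr$nose[, 2],
      center_x = tr$center[, 1], center_y = tr$center[, 2],
      tail_x = tr$tail[, 1], tail_y = tr$tail[, 2]),
      file.path(dir, "tracking.csv"))
  }
  invisible(dir)
}

.read_native_session <- function(dir, channel_map) {
  side <- jsonlite::fromJSON(file.path(dir, "session.json"),
                             simplifyVector = TRUE)
  dt <- data.table::fread(file.path(dir, "channels.csv"))
  gm <- as.logical(dt$gap_mask)
  want <- unname(channel_map[CANONICAL_CHANNELS])
  missing <- setdiff(want, names(dt))
  if (length(missing))
    stop(sprintf("channel %s missing",
                 CANONICAL_CHANNELS[match(missing, channel_map)][1]))
  samples <- as.matrix(dt[, want, with = FALSE])
  colnames(samples) <- CANONICAL_CHANNELS
  rec <- signal_record(samples, sample_rate = side$sample_rate,
                       start_time = side$start_time, gap_mask = gm)
  ev <- NULL
  if (!is.null(side$events) && NROW(side$events) > 0) {
    e <- side$events
    if (is.null(e$end)) e$end <- NA_real_
    if (is.null(e$cue_class)) e$cue_class <- NA_character_
    ev <- event_track(e$kind, e$start, as.numeric(e$end),
                      as.character(e$cue_class))
  }
  tr <- NULL
  tf <- file.path(dir, "tracking.csv")
  if (file.exists(tf)) {
    td <- data.table::fread(tf)
    tr <- tracking_trace(td$frame_time,
                         cbind(td$nose_x, td$nose_y),
                         cbind(td$center_x, td$center_y),
                         cbind(td$tail_x, td$tail_y))
  }
  list(record = rec, events = ev, tracking = tr, truth = side$truth)
}

#' Load a session referenced by a manifest
#'
#' Reads either the native CSV + JSON layout (a directory) or an EDF file
#' (read-only import; channels are re-ordered to the canonical
#' EEG1, EEG2, EMG, Resp order via the manifest's channel map). The
#' returned record has the gap mask applied ([apply_gap_mask()]).
#'
#' @param manifest A `session_manifest` whose `path` exists.
#' @return A list with `record`, `events`, `tracking`, `truth`, `manifest`.
#' @export
load_session <- function(manifest) {
  path <- manifest$path
  if (is.null(path) || !file.exists(path))
    stop("session path does not exist: ", path)
  if (dir.exists(path)) {
    out <- .read_native_session(path, manifest$channel_map)
  } else {
    rec <- read_edf(path, channel_map = manifest$channel_map)
    out <- list(record = rec, events = NULL, tracking = NULL, truth = NULL)
  }
  out$record <- apply_gap_mask(out$record)
  out$manifest <- manifest
  out
}
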