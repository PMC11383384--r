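# Minimal European Data Format (EDF) support. Import only covers what the
# pipeline needs: continuous signals, equal sampling rate across channels,
# 16-bit samples with the standard linear physical calibration. The writer
# exists so that EDF import can be exercised and round-tripped in tests.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Read an EDF file
#'
#' Supports continuous EDF recordings in which every signal shares one
#' sampling rate. Channels are re-ordered to the canonical
#' (EEG1, EEG2, EMG, Resp) order through `channel_map`; a channel named in
#' the map but absent from the file is a hard error.
#'
#' @param path EDF file path.
#' @param channel_map Named character vector, canonical name -> EDF label.
#' @return A `signal_record` (gap mask all-FALSE; EDF has no telemetry
#'   gap annotation).
#' @export
read_edf <- function(path, channel_map = setNames(CANONICAL_CHANNELS,
                                                  CANONICAL_CHANNELS)) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                               # header length, recomputed below
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1)
    stop("read_edf: channels with different sampling rates are unsupported")
  n_samp <- spr[1] * n_rec
  raw <- matrix(0L, n_samp, ns)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      raw[((r - 1) * spr[s] + 1):(r * spr[s]), s] <- v
    }
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  phys <- sweep(sweep(raw, 2, dmin), 2, gain, `*`)
  phys <- sweep(phys, 2, pmin, `+`)
  colnames(phys) <- labels
  want <- unname(channel_map[CANONICAL_CHANNELS])
  missing <- setdiff(want, labels)
  if (length(missing))
    stop(sprintf("channel %s missing",
                 names(channel_map)[match(missing[1], channel_map)]))
  signal_record(phys[, want, drop = FALSE],
                channel_names = CANONICAL_CHANNELS,
                sample_rate = spr[1] / rec_dur)
}

#' Write a signal record to EDF
#'
#' 16-bit quantization over each channel's observed range; record duration
#' 1 s. Intended for interoperability tests and data exchange, not archival.
#'
#' @param record A `signal_record` whose length is a whole number of seconds.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  x <- record$samples
  fs <- record$sample_rate
  if (nrow(x) %% fs != 0)
    stop("write_edf: record length must be a whole number of seconds")
  n_rec <- nrow(x) / fs
  ns <- ncol(x)
  pmin <- apply(x, 2, min); pmax <- apply(x, 2, max)
  same <- pmax - pmin < .Machine$double.eps
  pmax[same] <- pmin[same] + 1
  dmin <- -32768; dmax <- 32767
  dig <- round(sweep(sweep(x, 2, pmin), 2, (dmax - dmin) / (pmax - pmin), `*`) + dmin)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(s, width) writeChar(.edf_pad(s, width), con, eos = NULL)
  w("0", 8); w("X", 80); w("X", 80)
  w("01.01.00", 8); w("00.00.00", 8)
  w(256 * (ns + 1), 8); w("", 44)
  w(n_rec, 8); w("1", 8); w(ns, 4)
  for (lab in record$channel_names) w(lab, 16)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w("au", 8)
  for (v in pmin) w(format(v, digits = 6), 8)
  for (v in pmax) w(format(v, digits = 6), 8)
  for (i in seq_len(ns)) w(dmin, 8)
  for (i in seq_len(ns)) w(dmax, 8)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w(fs, 8)
  for (i in seq_len(ns)) w("", 32)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[((r - 1) * fs + 1):(r * fs), s]),
               con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
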