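# Locally-stationary spectral core: band filtering, five-cycle epoching,
# sine-taper multitaper spectral matrices, shrinkage regularization, partial
# coherence with null p-values and FDR control, normalized band power.

#' Zero-phase Butterworth band-pass filter (vector)
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param f_lo,f_hi Band edges, Hz; must lie strictly inside (0, fs/2).
#' @param order Filter order (applied twice by filtfilt).
#' @return Filtered vector of the same length.
#' @export
bandpass_filter <- function(x, fs, f_lo, f_hi, order = 4) {
  if (f_lo <= 0 || f_hi >= fs / 2)
    stop("band must lie strictly inside (0, Nyquist)")
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase band-pass filter (record)
#'
#' Filters every channel of a `signal_record`; the gap mask is preserved
#' unchanged.
#'
#' @param record A `signal_record`.
#' @param f_lo,f_hi Band edges, Hz.
#' @param order Filter order.
#' @return A filtered `signal_record`.
#' @export
bandpass <- function(record, f_lo, f_hi, order = 4) {
  out <- record
  out$samples <- apply(record$samples, 2, bandpass_filter,
                       fs = record$sample_rate, f_lo = f_lo, f_hi = f_hi,
                       order = order)
  colnames(out$samples) <- record$channel_names
  out
}

#' Non-overlapping epoch grid over the valid segments
#'
#' Epochs are anchored at the start of each contiguous unmasked segment and
#' tile it without overlap; a final fragment shorter than one epoch is
#' dropped, so no epoch ever straddles a masked interval.
#'
#' @param record A `signal_record`.
#' @param epoch_length Epoch length, seconds.
#' @return Data frame with `start_sample` (1-based) and `start_time` (s).
#' @export
epoch_grid <- function(record, epoch_length) {
  fs <- record$sample_rate
  nper <- round(epoch_length * fs)
  seg <- valid_segments(record, min_duration = epoch_length)
  if (nrow(seg) == 0)
    return(data.frame(start_sample = integer(), start_time = numeric()))
  starts <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    s0 <- seg$start_sample[i]
    nem <- (seg$end_sample[i] - s0) %/% nper
    if (nem == 0) integer() else s0 + nper * (0:(nem - 1))
  }))
  data.frame(start_sample = as.integer(starts),
             start_time = record$start_time + (starts - 1) / fs)
}

# tapered Fourier coefficients of one epoch at selected one-sided bins.
# Returns an array bins x channels x tapers.
.taper_fft <- function(X, tapers, bins) {
  K <- ncol(tapers)
  out <- array(0 + 0i, dim = c(length(bins), ncol(X), K))
  for (k in seq_len(K))
    out[, , k] <- mvfft(X * tapers[, k])[bins, , drop = FALSE]
  out
}

# average cross-periodogram over a taper subset: bins x p x p
.smat_from_J <- function(J, kset) {
  p <- dim(J)[2]
  nb <- dim(J)[1]
  S <- array(0 + 0i, dim = c(nb, p, p))
  for (k in kset) {
    Jk <- J[, , k, drop = FALSE]
    for (b in seq_len(nb))
      S[b, , ] <- S[b, , ] + outer(Jk[b, , 1], Conj(Jk[b, , 1]))
  }
  S / length(kset)
}

#' Multitaper spectral matrix of one epoch
#'
#' Thomson multitaper estimate with orthonormal sine tapers: the average
#' over K tapered cross-periodograms, scaled as a one-sided spectral
#' density (2 / (K fs) sum_k J_k J_k^H), Hermitian at every frequency.
#'
#' @param X Numeric matrix, samples x channels (N >= K, p >= 2 channels).
#' @param fs Sampling rate, Hz.
#' @param n_tapers Taper count; default `taper_count(ncol(X))`.
#' @return List of class `spectral_matrix` with `frequencies` (Hz), `S`
#'   (complex array p x p x n_freq), `fs`, `n_tapers`, `n_samples`,
#'   `regularization` (0 until [regularize()] is applied).
#' @export
multitaper_spectral_matrix <- function(X, fs, n_tapers = taper_count(ncol(X))) {
  X <- as.matrix(X)
  N <- nrow(X); p <- ncol(X)
  if (p < 2) stop("need at least 2 channels")
  if (N < n_tapers) stop("epoch shorter than the taper count")
  tapers <- sine_tapers(N, n_tapers)
  nf <- N %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / N
  J <- .taper_fft(X, tapers, seq_len(nf))
  Sb <- .smat_from_J(J, seq_len(n_tapers)) * (2 / fs)
  S <- array(0 + 0i, dim = c(p, p, nf))
  for (b in seq_len(nf)) S[, , b] <- Sb[b, , ]
  structure(list(frequencies = freqs, S = S, fs = fs, n_tapers = n_tapers,
                 n_samples = N, regularization = 0),
            class = "spectral_matrix")
}

#' Shrinkage regularization of a spectral matrix estimate
#'
#' Convex shrinkage toward the scaled identity at every frequency:
#' S_reg = (1 - w) S + w (tr(S) / p) I. Guarantees invertibility for
#' w > 0 whenever tr(S) > 0.
#'
#' @param S A `spectral_matrix`.
#' @param weight Shrinkage weight in `[0, 1]` (default 0.05).
#' @return The regularized `spectral_matrix` (weight recorded).
#' @export
regularize <- function(S, weight = 0.05) {
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]")
  p <- dim(S$S)[1]
  for (b in seq_len(dim(S$S)[3])) {
    M <- S$S[, , b]
    S$S[, , b] <- (1 - weight) * M +
      weight * (Re(sum(diag(M))) / p) * diag(p)
  }
  S$regularization <- weight
  S
}

# partial coherence matrix from one p x p spectral matrix
.pcoh_of_S <- function(M) {
  G <- solve(M)
  d <- Re(diag(G))
  C <- Mod(G)^2 / outer(d, d)
  diag(C) <- 1
  C
}

# ordinary magnitude-squared coherence from one p x p spectral matrix
.coh_of_S <- function(M) {
  d <- Re(diag(M))
  C <- Mod(M)^2 / outer(d, d)
  diag(C) <- 1
  C
}

.band_bins <- function(frequencies, band) {
  which(frequencies >= band$f_lo & frequencies < band$f_hi)
}

#' Band-averaged partial coherence
#'
#' Pairwise partial coherence |G_jk|^2 / (G_jj G_kk) from the inverse
#' spectral matrix G at each frequency bin whose centre lies in
#' `[f_lo, f_hi)`, averaged over the band. With two channels this reduces
#' to the ordinary magnitude-squared coherence.
#'
#' @param S A (regularized) `spectral_matrix`.
#' @param band Band name or definition; NULL averages over all bins.
#' @return Symmetric p x p matrix of band-averaged partial coherences
#'   (unit diagonal).
#' @export
partial_coherence <- function(S, band = NULL) {
  bins <- if (is.null(band)) seq_along(S$frequencies)
          else .band_bins(S$frequencies, band_definition(band))
  if (length(bins) == 0) stop("no frequency bins inside the band")
  p <- dim(S$S)[1]
  out <- matrix(0, p, p)
  for (b in bins) {
    M <- S$S[, , b]
    C <- tryCatch(.pcoh_of_S(M), error = function(e)
      stop("spectral matrix not invertible; apply regularize() first"))
    out <- out + C
  }
  out <- out / length(bins)
  dimnames(out) <- dimnames(S$S)[1:2]
  out
}

#' Band-averaged ordinary coherence
#'
#' Magnitude-squared coherence |S_jk|^2 / (S_jj S_kk), band-averaged as in
#' [partial_coherence()]. Used for contrasting direct (partial) with
#' marginal association.
#'
#' @inheritParams partial_coherence
#' @return Symmetric p x p matrix.
#' @export
band_coherence <- function(S, band = NULL) {
  bins <- if (is.null(band)) seq_along(S$frequencies)
          else .band_bins(S$frequencies, band_definition(band))
  if (length(bins) == 0) stop("no frequency bins inside the band")
  p <- dim(S$S)[1]
  out <- matrix(0, p, p)
  for (b in bins) out <- out + .coh_of_S(S$S[, , b])
  out / length(bins)
}

#' Null p-value for a partial coherence estimate
#'
#' Under H0 (partial coherence = 0) the single-bin sine-taper estimate with
#' K tapers, conditioned on p - 2 remaining channels, follows a
#' Beta(1, K - (p - 2) - 1) law, giving
#' p = (1 - estimate)^(K - (p - 2) - 1). The effective degrees of freedom
#' must satisfy 2K > 2(p - 2) + 2.
#'
#' @param estimate Partial coherence estimate(s) in `[0, 1]`.
#' @param n_tapers Taper count K (6 for the canonical record).
#' @param p_channels Number of channels p (4 for the canonical record).
#' @return p-value(s) in `[0, 1]`.
#' @export
pcoh_pvalue <- function(estimate, n_tapers, p_channels) {
  dof <- n_tapers - (p_channels - 2) - 1
  if (dof < 1)
    stop("insufficient degrees of freedom: need 2K > 2(p - 2) + 2")
  if (any(estimate < 0 | estimate > 1)) stop("estimate must lie in [0, 1]")
  (1 - estimate)^dof
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up FDR control over the pooled family (all pairs x all epochs).
#'
#' @param p_values Numeric vector of p-values.
#' @param q Target false discovery rate (0.05).
#' @return Logical vector: TRUE where significant after FDR adjustment.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical())
  p.adjust(p_values, method = "BH") <= q
}

#' Normalized spectral power over 0.5--20 Hz
#'
#' Diagonal of unregularized multitaper spectral matrices over delta-length
#' epochs, averaged over epochs, restricted to `range`, and normalized so
#' the average power over the range is 1 for every channel.
#'
#' @param record A `signal_record` longer than one delta epoch.
#' @param range Frequency range, Hz.
#' @return Data frame with `frequency` and one column per channel.
#' @export
band_power <- function(record, range = c(0.5, 20)) {
  fs <- record$sample_rate
  ep <- epoch_length_for_band("delta")
  grid <- epoch_grid(record, ep)
  if (nrow(grid) == 0) stop("record shorter than one delta epoch")
  nper <- round(ep * fs)
  p <- ncol(record$samples)
  K <- taper_count(p)
  tapers <- sine_tapers(nper, K)
  nf <- nper %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / nper
  keep <- freqs >= range[1] & freqs <= range[2]
  acc <- matrix(0, sum(keep), p)
  for (i in seq_len(nrow(grid))) {
    idx <- grid$start_sample[i]:(grid$start_sample[i] + nper - 1)
    J <- .taper_fft(record$samples[idx, , drop = FALSE], tapers, which(keep))
    psd <- matrix(0, sum(keep), p)
    for (k in seq_len(K)) psd <- psd + Mod(J[, , k])^2
    acc <- acc + psd * (2 / (K * fs))
  }
  acc <- acc / nrow(grid)
  acc <- sweep(acc, 2, colMeans(acc), `/`)
  out <- data.frame(frequency = freqs[keep])
  out[record$channel_names] <- acc
  out
}
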