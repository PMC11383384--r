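# Small VAR(1) generator with closed-form spectrum. Provided solely as an
# independent oracle for the partial-coherence estimators: the analytic
# spectral matrix of a known VAR system gives exact band-averaged partial
# coherences to compare estimates against.

#' Simulate a stationary VAR(1) process
#'
#' x_t = A x_{t-1} + e_t with e_t ~ N(0, Sigma). Burn-in discarded.
#'
#' @param A p x p coefficient matrix (spectral radius < 1).
#' @param Sigma p x p innovation covariance (default identity).
#' @param n Number of samples to return.
#' @param burn Burn-in samples (500).
#' @return Numeric matrix n x p. Seed the RNG before calling for
#'   reproducibility.
#' @export
simulate_var <- function(A, Sigma = diag(nrow(A)), n, burn = 500) {
  p <- nrow(A)
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1)
    stop("VAR coefficient matrix must be stable (spectral radius < 1)")
  L <- chol(Sigma)
  eps <- matrix(rnorm((n + burn) * p), n + burn, p) %*% L
  X <- matrix(0, n + burn, p)
  for (t in 2:(n + burn)) X[t, ] <- A %*% X[t - 1, ] + eps[t, ]
  X[(burn + 1):(burn + n), , drop = FALSE]
}

#' Analytic spectral matrix of a VAR(1) process
#'
#' S(f) = H(f) Sigma H(f)^H with H(f) = (I - A e^{-i 2 pi f / fs})^{-1},
#' scaled as a one-sided density (2 / fs) to match
#' [multitaper_spectral_matrix()]. Partial coherence derived from it is
#' scale-free, so the convention does not affect oracle comparisons.
#'
#' @param A,Sigma VAR(1) parameters.
#' @param freqs Frequencies, Hz.
#' @param fs Sampling rate, Hz.
#' @return A `spectral_matrix` object over `freqs`.
#' @export
var_spectral_matrix <- function(A, Sigma = diag(nrow(A)), freqs, fs) {
  p <- nrow(A)
  S <- array(0 + 0i, dim = c(p, p, length(freqs)))
  for (i in seq_along(freqs)) {
    om <- 2 * pi * freqs[i] / fs
    H <- solve(diag(p) - A * exp(-1i * om))
    S[, , i] <- (2 / fs) * H %*% Sigma %*% Conj(t(H))
  }
  structure(list(frequencies = freqs, S = S, fs = fs,
                 n_tapers = NA_integer_, n_samples = NA_integer_,
                 regularization = 0),
            class = "spectral_matrix")
}

#' Pooled multitaper partial coherence of a stationary record
#'
#' Averages epoch-wise multitaper spectral matrices over the whole record
#' before deriving partial coherence, for stationary analyses (oracle
#' comparisons, long baseline segments).
#'
#' @param X Numeric matrix samples x channels.
#' @param fs Sampling rate, Hz.
#' @param band Band name or definition.
#' @param epoch_length Epoch length, s; default the band's five-cycle
#'   length.
#' @param weight Shrinkage weight (0.05).
#' @return List with `pcoh` and `coherence` (p x p band-averaged matrices),
#'   `n_epochs`, `n_tapers`.
#' @export
pooled_band_pcoh <- function(X, fs, band,
                             epoch_length = epoch_length_for_band(band),
                             weight = 0.05) {
  bd <- band_definition(band)
  nper <- round(epoch_length * fs)
  p <- ncol(X)
  K <- taper_count(p)
  tapers <- sine_tapers(nper, K)
  nf <- nper %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / nper
  bins <- .band_bins(freqs, bd)
  nep <- nrow(X) %/% nper
  if (nep < 1) stop("record shorter than one epoch")
  Spool <- array(0 + 0i, dim = c(length(bins), p, p))
  for (e in seq_len(nep)) {
    idx <- ((e - 1) * nper + 1):(e * nper)
    J <- .taper_fft(X[idx, , drop = FALSE], tapers, bins)
    Spool <- Spool + .smat_from_J(J, seq_len(K))
  }
  Spool <- Spool / nep
  pc <- matrix(0, p, p); co <- matrix(0, p, p)
  for (b in seq_along(bins)) {
    S <- Spool[b, , ]
    co <- co + .coh_of_S(S)
    S <- (1 - weight) * S + weight * (Re(sum(diag(S))) / p) * diag(p)
    pc <- pc + .pcoh_of_S(S)
  }
  list(pcoh = pc / length(bins), coherence = co / length(bins),
       n_epochs = nep, n_tapers = K)
}
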