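# Evolving partial coherence and event-locked inference: the per-epoch
# pipeline (bandpass -> epoch -> multitaper -> regularize -> partial
# coherence -> p-values -> FDR), lagged event regression, baseline
# connectivity graphs and the EMG-respiration mixed-model confound check.

.REPORTED_PAIRS <- c("EEG1-EEG2", "EEG1-Resp", "EEG2-Resp")

.pair_names <- function(channels) {
  cmb <- utils::combn(channels, 2)
  paste(cmb[1, ], cmb[2, ], sep = "-")
}

#' Evolving partial coherence of a session
#'
#' Runs the full locally-stationary pipeline for one band: zero-phase
#' band-pass filtering, non-overlapping epoching at the band's five-cycle
#' epoch length (epochs never straddle telemetry gaps), sine-taper
#' multitaper spectral matrices, shrinkage regularization, band-averaged
#' partial coherence per channel pair, null p-values, and
#' Benjamini-Hochberg FDR flags over the pooled pairs-by-epochs family.
#'
#' Two estimates are reported per epoch and pair: `estimate`, the
#' band-averaged partial coherence from the regularized spectral matrix
#' (always in `[0, 1]`), and `estimate_debiased`, a leave-one-taper-out
#' jackknife debiased version used by [lagged_event_regression()] (it may
#' leave `[0, 1]` in noise). The p-value is computed from the unregularized
#' estimate at the bin nearest the band centre of the *unfiltered* epoch,
#' where the Beta null law is exactly calibrated (band-pass filtering ahead
#' of the tapers makes the taper coefficients heteroscedastic and the law
#' anticonservative).
#'
#' @param record A `signal_record` with the canonical four channels.
#' @param band Band name or definition.
#' @param weight Shrinkage weight (0.05), recorded in the output.
#' @param pairs `"reported"` for the EEG1/EEG2/Resp pairs (conditioned on
#'   EMG), or `"all"` for all 6 pairs.
#' @param q FDR level (0.05).
#' @param debias Compute the jackknife column (TRUE).
#' @return Data frame of class `evolving_pcoh`: `epoch_start`, `band`,
#'   `pair`, `estimate`, `estimate_debiased`, `p_value`,
#'   `fdr_significant`; attributes `band`, `epoch_length`, `n_tapers`,
#'   `regularization`, `n_epochs`.
#' @export
evolving_pcoh <- function(record, band, weight = 0.05,
                          pairs = c("reported", "all"), q = 0.05,
                          debias = TRUE) {
  pairs <- match.arg(pairs)
  bd <- band_definition(band)
  fs <- record$sample_rate
  filt <- bandpass(record, bd$f_lo, bd$f_hi)
  ep_len <- epoch_length_for_band(bd)
  grid <- epoch_grid(record, ep_len)
  if (nrow(grid) == 0) stop("no full epochs inside the valid segments")
  nper <- round(ep_len * fs)
  p <- ncol(record$samples)
  K <- taper_count(p)
  tapers <- sine_tapers(nper, K)
  nf <- nper %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / nper
  bins <- .band_bins(freqs, bd)
  if (length(bins) == 0) stop("epoch too short: no frequency bin in band")
  centre_bin <- bins[which.min(abs(freqs[bins] - (bd$f_lo + bd$f_hi) / 2))]
  use_bins <- bins
  bpos <- seq_along(bins)

  all_names <- .pair_names(record$channel_names)
  keep_pairs <- if (pairs == "reported")
    intersect(all_names, .REPORTED_PAIRS) else all_names
  ut <- upper.tri(matrix(0, p, p))

  nep <- nrow(grid)
  res <- vector("list", nep)
  for (e in seq_len(nep)) {
    idx <- grid$start_sample[e]:(grid$start_sample[e] + nper - 1L)
    X <- filt$samples[idx, , drop = FALSE]
    J <- .taper_fft(X, tapers, use_bins)
    Jraw <- .taper_fft(record$samples[idx, , drop = FALSE], tapers,
                       centre_bin)
    # per-bin taper outer products, accumulated once
    OP <- vector("list", length(use_bins))
    for (b in seq_along(use_bins)) {
      OP[[b]] <- lapply(seq_len(K), function(k) outer(J[b, , k], Conj(J[b, , k])))
    }
    band_pcoh <- function(kset) {
      acc <- matrix(0, p, p)
      for (b in bpos) {
        S <- Reduce(`+`, OP[[b]][kset]) / length(kset)
        S <- (1 - weight) * S + weight * (Re(sum(diag(S))) / p) * diag(p)
        acc <- acc + .pcoh_of_S(S)
      }
      acc / length(bpos)
    }
    full <- band_pcoh(seq_len(K))
    est_jk <- full
    if (debias) {
      loo <- array(0, dim = c(p, p, K))
      for (k in seq_len(K)) loo[, , k] <- band_pcoh(setdiff(seq_len(K), k))
      est_jk <- K * full - (K - 1) * apply(loo, c(1, 2), mean)
    }
    Sc <- Reduce(`+`, lapply(seq_len(K), function(k)
      outer(Jraw[1, , k], Conj(Jraw[1, , k])))) / K
    pc_centre <- tryCatch(.pcoh_of_S(Sc), error = function(err) {
      Sr <- (1 - 1e-6) * Sc + 1e-6 * (Re(sum(diag(Sc))) / p) * diag(p)
      .pcoh_of_S(Sr)
    })
    pv <- pcoh_pvalue(pmin(pmax(pc_centre[ut], 0), 1), K, p)
    res[[e]] <- data.frame(
      epoch_start = grid$start_time[e], band = bd$name, pair = all_names,
      estimate = full[ut], estimate_debiased = est_jk[ut], p_value = pv)
  }
  out <- do.call(rbind, res)
  out <- out[out$pair %in% keep_pairs, , drop = FALSE]
  out$fdr_significant <- fdr_adjust(out$p_value, q)
  rownames(out) <- NULL
  attr(out, "band") <- bd$name
  attr(out, "epoch_length") <- ep_len
  attr(out, "n_tapers") <- K
  attr(out, "n_channels") <- p
  attr(out, "regularization") <- weight
  attr(out, "n_epochs") <- nep
  class(out) <- c("evolving_pcoh", "data.frame")
  out
}

#' @export
print.evolving_pcoh <- function(x, ...) {
  cat(sprintf("<evolving_pcoh> band %s, %d epochs x %d pairs (epoch %.2f s, K = %d, w = %.2f)\n",
              attr(x, "band"), attr(x, "n_epochs"),
              length(unique(x$pair)), attr(x, "epoch_length"),
              attr(x, "n_tapers"), attr(x, "regularization")))
  cat(sprintf("  FDR-significant records: %d / %d\n",
              sum(x$fdr_significant), nrow(x)))
  invisible(x)
}

#' @export
summary.evolving_pcoh <- function(object, ...) {
  agg <- stats::aggregate(estimate ~ pair, data = object, FUN = mean)
  names(agg)[2] <- "mean_estimate"
  agg$n_significant <- stats::aggregate(fdr_significant ~ pair, data = object,
                                        FUN = sum)$fdr_significant
  agg
}

#' @export
plot.evolving_pcoh <- function(x, ...) {
  prs <- unique(x$pair)
  cols <- seq_along(prs)
  graphics::plot(NULL, xlim = range(x$epoch_start), ylim = c(0, 1),
                 xlab = "epoch start (s)", ylab = "partial coherence",
                 main = sprintf("evolving partial coherence (%s band)",
                                attr(x, "band")), ...)
  for (i in seq_along(prs)) {
    d <- x[x$pair == prs[i], ]
    graphics::lines(d$epoch_start, d$estimate, col = cols[i])
  }
  graphics::legend("topright", legend = prs, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Lagged event regression on evolving partial coherence
#'
#' Regresses epoch-wise partial coherence on lag indicators around event
#' starts: the epoch containing an event start is lag 0, the three epochs
#' on either side are lags -3..+3, and all epochs more than three epochs
#' away from every event form the baseline (reference) class. One
#' regression per channel pair; coefficients are the change from baseline.
#' Events without full +/-3-epoch context are dropped and counted.
#'
#' @param pcoh An `evolving_pcoh` data frame.
#' @param events An `event_track` (bout starts or odor introductions).
#' @param n_lags Lags on each side (3).
#' @param use_debiased Regress the jackknife-debiased estimates (TRUE).
#' @return Data frame of class `lag_regression` with `band`, `pair`, `lag`,
#'   `estimate`, `se`, `p_value`; attribute `n_dropped_events`.
#' @export
lagged_event_regression <- function(pcoh, events, n_lags = 3,
                                    use_debiased = TRUE) {
  ep_starts <- sort(unique(pcoh$epoch_start))
  ep_len <- attr(pcoh, "epoch_length")
  nE <- length(ep_starts)
  ev <- events$start
  lag_of_epoch <- rep(NA_integer_, nE)
  dropped <- 0L
  for (t0 in ev) {
    # tolerance so an event nominally on an epoch boundary is assigned to
    # the epoch it opens, not the one it closes
    e0 <- findInterval(t0 + ep_len * 1e-6, ep_starts)
    if (e0 < 1 || t0 >= ep_starts[e0] + ep_len + 1e-9) { dropped <- dropped + 1L; next }
    if (e0 - n_lags < 1 || e0 + n_lags > nE) { dropped <- dropped + 1L; next }
    for (l in -n_lags:n_lags) {
      if (is.na(lag_of_epoch[e0 + l])) lag_of_epoch[e0 + l] <- l
    }
  }
  if (all(!is.na(lag_of_epoch)))
    stop("no baseline epochs outside the event windows")
  if (dropped == length(ev))
    stop("no event with full lag context")
  lev <- c("baseline", as.character(-n_lags:n_lags))
  lagf <- factor(ifelse(is.na(lag_of_epoch), "baseline",
                        as.character(lag_of_epoch)), levels = lev)
  ycol <- if (use_debiased) "estimate_debiased" else "estimate"
  res <- list()
  for (pr in unique(pcoh$pair)) {
    d <- pcoh[pcoh$pair == pr, ]
    d <- d[match(ep_starts, d$epoch_start), ]
    fit <- lm(d[[ycol]] ~ lagf)
    sm <- summary(fit)$coefficients
    rows <- paste0("lagf", as.character(-n_lags:n_lags))
    got <- match(rows, rownames(sm))
    res[[pr]] <- data.frame(
      band = attr(pcoh, "band"), pair = pr, lag = -n_lags:n_lags,
      estimate = sm[got, "Estimate"], se = sm[got, "Std. Error"],
      p_value = sm[got, "Pr(>|t|)"])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_dropped_events") <- dropped
  class(out) <- c("lag_regression", "data.frame")
  out
}

#' Edge rule for the baseline connectivity graph
#'
#' Pure function of (estimate, p): an edge is drawn iff the pooled partial
#' coherence exceeds 0.15; it is solid (significant) iff additionally
#' p < 0.05.
#'
#' @param estimate Pooled partial coherence estimate(s).
#' @param p_value Pooled p-value(s).
#' @param estimate_threshold Minimum estimate for an edge (0.15).
#' @param alpha Significance level (0.05).
#' @return Data frame with logical `drawn` and `significant`.
#' @export
graph_edge_rule <- function(estimate, p_value, estimate_threshold = 0.15,
                            alpha = 0.05) {
  data.frame(drawn = estimate > estimate_threshold,
             significant = estimate > estimate_threshold & p_value < alpha)
}

#' Baseline weighted connectivity graph over still epochs
#'
#' Pools the spectral matrices of all epochs classified as still (no
#' overlap with a moving EMG bin), derives band-averaged partial coherence
#' per channel pair from the pooled estimate, computes pooled p-values
#' (taper count times pooled epochs degrees of freedom), and applies the
#' edge rule: draw if estimate > 0.15, solid if p < 0.05.
#'
#' @param record A `signal_record`.
#' @param band Band name or definition.
#' @param movement A `movement_track` from [classify_movement()].
#' @param weight Shrinkage weight (0.05).
#' @return List of class `connectivity_graph`: `nodes`, `edges` (pair,
#'   weight, p_value, drawn, significant), `band`, `n_still_epochs`.
#' @export
build_connectivity_graph <- function(record, band, movement, weight = 0.05) {
  bd <- band_definition(band)
  fs <- record$sample_rate
  filt <- bandpass(record, bd$f_lo, bd$f_hi)
  ep_len <- epoch_length_for_band(bd)
  grid <- epoch_grid(record, ep_len)
  nper <- round(ep_len * fs)
  mv <- movement[movement$moving, , drop = FALSE]
  bin_half <- 1  # movement bins are 2 s
  still <- vapply(seq_len(nrow(grid)), function(e) {
    s0 <- grid$start_time[e]; s1 <- s0 + ep_len
    !any(mv$bin_center + bin_half > s0 & mv$bin_center - bin_half < s1)
  }, logical(1))
  if (!any(still)) stop("no still epochs")
  p <- ncol(record$samples)
  K <- taper_count(p)
  tapers <- sine_tapers(nper, K)
  nf <- nper %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / nper
  bins <- .band_bins(freqs, bd)
  Spool <- array(0 + 0i, dim = c(length(bins), p, p))
  nst <- 0L
  for (e in which(still)) {
    idx <- grid$start_sample[e]:(grid$start_sample[e] + nper - 1L)
    J <- .taper_fft(filt$samples[idx, , drop = FALSE], tapers, bins)
    Spool <- Spool + .smat_from_J(J, seq_len(K))
    nst <- nst + 1L
  }
  Spool <- Spool / nst
  est <- matrix(0, p, p)
  for (b in seq_along(bins)) {
    S <- Spool[b, , ]
    S <- (1 - weight) * S + weight * (Re(sum(diag(S))) / p) * diag(p)
    est <- est + .pcoh_of_S(S)
  }
  est <- est / length(bins)
  ut <- upper.tri(est)
  pv <- pcoh_pvalue(pmin(pmax(est[ut], 0), 1), K * nst, p)
  pair <- .pair_names(record$channel_names)
  rule <- graph_edge_rule(est[ut], pv)
  edges <- data.frame(pair = pair, weight = est[ut], p_value = pv,
                      drawn = rule$drawn, significant = rule$significant)
  structure(list(nodes = record$channel_names, edges = edges,
                 band = bd$name, n_still_epochs = nst),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> band %s, %d still epochs\n",
              x$band, x$n_still_epochs))
  e <- x$edges[x$edges$drawn, , drop = FALSE]
  if (nrow(e) == 0) {
    cat("  no edges\n")
  } else {
    for (i in seq_len(nrow(e)))
      cat(sprintf("  %s  weight %.3f  %s\n", e$pair[i], e$weight[i],
                  if (e$significant[i]) "solid (p < 0.05)" else "dashed"))
  }
  invisible(x)
}

#' Export a connectivity graph as DOT
#' @param graph A `connectivity_graph`.
#' @return A character scalar of DOT source.
#' @export
graph_as_dot <- function(graph) {
  e <- graph$edges[graph$edges$drawn, , drop = FALSE]
  lines <- c("graph connectivity {")
  for (n in graph$nodes) lines <- c(lines, sprintf("  \"%s\";", n))
  if (nrow(e)) {
    ab <- strsplit(e$pair, "-", fixed = TRUE)
    for (i in seq_len(nrow(e)))
      lines <- c(lines, sprintf(
        "  \"%s\" -- \"%s\" [penwidth=%.2f, style=%s];",
        ab[[i]][1], ab[[i]][2], 1 + 6 * e$weight[i],
        if (e$significant[i]) "solid" else "dashed"))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' EMG-respiration mixed-model confound check
#'
#' Random-intercept regression of per-bin sniff rate on per-bin EMG RMS
#' with animal as the random effect
#' (sniff_rate ~ emg_rms + (1 | animal_id)); the derived correlation is the
#' fixed coefficient scaled by SD(emg)/SD(sniff). With a single animal the
#' model degrades to ordinary least squares (warning). Run on all bins or
#' on the still/moving subsets.
#'
#' @param sniff_rate Per-bin sniff rate, Hz.
#' @param emg_rms Per-bin EMG RMS.
#' @param animal_id Per-bin animal label.
#' @param subset `"all"`, `"still"` or `"moving"`.
#' @param moving Logical per bin; required for the still/moving subsets.
#' @return List of class `emg_resp_mixed_model`: `coefficient`,
#'   `correlation`, `p_value`, `subset`, `n_bins`, `n_animals`, `model`.
#' @export
emg_resp_mixed_model <- function(sniff_rate, emg_rms, animal_id,
                                 subset = c("all", "still", "moving"),
                                 moving = NULL) {
  subset <- match.arg(subset)
  if (subset != "all") {
    if (is.null(moving)) stop("moving flags required for subset analyses")
    sel <- if (subset == "moving") moving else !moving
    sniff_rate <- sniff_rate[sel]; emg_rms <- emg_rms[sel]
    animal_id <- animal_id[sel]
  }
  ok <- !is.na(sniff_rate) & !is.na(emg_rms)
  sniff_rate <- sniff_rate[ok]; emg_rms <- emg_rms[ok]
  animal_id <- animal_id[ok]
  if (sd(emg_rms) < 1e-12) stop("constant predictor")
  d <- data.frame(sniff = sniff_rate, emg = emg_rms,
                  animal = factor(animal_id))
  n_animals <- nlevels(d$animal)
  if (n_animals >= 2) {
    fit <- lmerTest::lmer(sniff ~ emg + (1 | animal), data = d)
    sm <- summary(fit)$coefficients
    beta <- sm["emg", "Estimate"]
    pval <- sm["emg", "Pr(>|t|)"]
  } else {
    warning("single animal: degrading to ordinary least-squares regression")
    fit <- lm(sniff ~ emg, data = d)
    sm <- summary(fit)$coefficients
    beta <- sm["emg", "Estimate"]
    pval <- sm["emg", "Pr(>|t|)"]
  }
  structure(list(coefficient = beta,
                 correlation = beta * sd(d$emg) / sd(d$sniff),
                 p_value = pval, subset = subset, n_bins = nrow(d),
                 n_animals = n_animals, model = fit),
            class = "emg_resp_mixed_model")
}

#' @export
print.emg_resp_mixed_model <- function(x, ...) {
  cat(sprintf("<emg_resp_mixed_model> subset %s: n = %d bins, %d animals\n",
              x$subset, x$n_bins, x$n_animals))
  cat(sprintf("  coefficient %.4f, correlation %.3f, p = %.3g\n",
              x$coefficient, x$correlation, x$p_value))
  invisible(x)
}
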