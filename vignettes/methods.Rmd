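---
title: "Methods: respiration-brain state coupling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiration-brain state coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sniffsync)
```

sniffsync analyses synchronized four-channel physiology recordings
(EEG1, EEG2, EMG, Resp) from freely moving mice, where Resp is a thoracic
pressure signal whose negative deflections mark inhalation. This vignette
documents the statistical machinery, the defaults and why they hold, what
the synthetic-session generator does and does not emulate, and the design
choices made where more than one defensible option existed.

## Session model

A session is a `signal_record`: a samples-by-channels matrix on one clock
(canonically 400 Hz), plus a logical gap mask marking samples where the
respiration telemetry was off (the implanted sensor is battery limited and
is only on for part of a session). All analysis respects the mask through
one rule: epochs and windows are drawn only from maximal contiguous
unmasked segments, anchored at each segment start, and a fragment shorter
than one epoch is dropped rather than padded. Time is in seconds from
record start and all intervals are half-open `[start, end)`.

On disk a session is a CSV channel table plus a JSON sidecar (events,
manifest, ground truth). Channel values are written with 17 significant
digits so a write/load round trip reproduces doubles exactly. EDF import
is supported read-only for interoperability; EDF itself quantizes samples
to 16 bits, so an EDF round trip is exact only to that quantization.

## Respiration analyses

**Rolling dominant frequency.** Each 1-s window (50-ms shift) is
standardized, linearly detrended, and passed through an autocorrelation
routine; the reciprocal of the first qualifying autocorrelation peak is
the dominant frequency. Three details matter:

* *Per-lag Pearson normalization.* The plain sample autocorrelation of a
  window holding few cycles carries a phase-dependent edge term that is
  periodic at the signal's own period, which can displace the first peak
  by many samples at low frequencies. We therefore compute, at each lag,
  the Pearson correlation between the two overlapping segments. For a
  periodic window the two segments at the true period are identical, so
  the peak sits exactly there, independent of window phase.
* *Qualifying peak.* First local maximum after the first zero crossing,
  with lag at least 1/15 s (capping detectable frequency at 15 Hz, well
  above mouse sniffing), correlation at least 0.2, and additionally at
  least `4 / sqrt(overlap)` - a significance floor that suppresses
  spurious long-lag peaks where the overlapping segments are short.
  Without it, pure noise windows systematically report 1-1.5 Hz.
* *Sub-sample refinement.* The peak lag is refined by parabolic
  interpolation of the three surrounding correlations; windows with no
  qualifying peak, or zero variance, yield a missing value (constant
  windows also log a warning).

**Inhalation peaks.** Troughs of the 1-15 Hz zero-phase band-passed
signal, subject to a minimum spacing of 1/15 s and a depth prominence of
at least 25% of the median trough depth. Because band-passed noise also
wiggles, troughs are additionally gated on periodicity: a trough is kept
only if it falls inside a window where the rolling estimator found a
dominant frequency. On white noise this leaves a near-empty train; on
sniff-like signals it changes nothing.

**Sensor agreement.** `relative_error()` implements
(f_thoracic - f_flow) / f_flow per window, averaged per trial, with the
population mean and SD across trials; windows with missing or zero flow
frequency are excluded and counted. `peak_lag()` pairs each flow peak
with the nearest thoracic peak within half the median flow inter-peak
interval and reports flow-minus-thoracic lags, so flow leading pressure
gives negative lags.

**Bout-aligned trials.** A trial spans 3 s before a bout start to 3 s
after its end; bouts with less than 3 s of prior recording are discarded,
as are trials whose baseline is more than half missing. The baseline is
the mean frequency over the first 500 ms of the trial (taken literally at
the start of the 3-s pre-window) and the exploration frequency the mean
over the first second of the bout. Note one structural bias: 1-s analysis
windows centred shortly after bout onset still contain pre-bout samples,
so a step increase is recovered slightly compressed (about 0.2 Hz for a
3-Hz step); this is inherent to the window length, not to the estimator.

**Intersniff statistics.** Intervals between consecutive inhalation
peaks, each assigned to the vigilance state of the 5-s epoch holding its
earlier peak; the per-state mean frequency is defined as the reciprocal
of the mean interval, which makes the summary reproducible.

## Vigilance scoring

Per 5-s epoch the scorer computes delta (1-4 Hz) and theta (4-10 Hz)
power density on the mean of the two EEG channels and the EMG RMS, then
applies: EMG above 2x the session median epoch RMS -> wake; else delta
above 1.5x the session median delta -> NREM; else theta/delta above 1 ->
REM; else wake. The scoring theta band (4-10 Hz) is deliberately a
different constant from the coherence theta band (4-8 Hz). Thresholds are
relative to session medians, which makes labels exactly invariant to
rescaling either channel but assumes no single state dominates much more
than half the session - in an almost-all-NREM recording the median delta
is itself the NREM level and the delta rule misfires. For such recordings
pass explicit `thresholds`. REM-to-NREM transitions, which mice
essentially never produce, are counted as a QC flag, never coerced.

Sleep-odor trials follow a fixed window layout: sensor on 10 s after NREM
onset (for one minute), odor 10 s later, a 20-s half-open transition
window from odor time, and 5-s comparison windows either side of odor
time compared by paired t test (identical windows give p = 1 by
convention rather than 0/0).

## The locally stationary spectral core

Each band (delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30 Hz) is analysed
on its own epoch grid, sized to hold about five cycles of the band
centre: 5 divided by the arithmetic band midpoint, rounded to two
decimals - 2.22, 0.83, 0.5 s - with beta pinned at 0.25 s (the published
value; the rule itself gives 0.238). Channels are zero-phase Butterworth
band-passed (order 4, applied forward and backward), epoched, and each
epoch's spectral matrix is estimated with K = ceiling(1.5 p) orthonormal
sine tapers (6 for p = 4), scaled as a one-sided density. Shrinkage
regularization `(1 - w) S + w (tr S / p) I` with default w = 0.05
guarantees invertibility; w is recorded in every output. Partial
coherence between channels j and k is `|G_jk|^2 / (G_jj G_kk)` from the
inverse spectral matrix G, averaged over the frequency bins whose centres
fall in the band; with two channels it reduces to ordinary coherence.
With four channels there are six pairs; reported sets default to the
EEG1/EEG2/Resp pairs, each conditioned on the remaining channels
including EMG.

**Null p-values.** Under independence the single-bin, unregularized
partial-coherence estimate follows Beta(1, K - (p - 2) - 1), giving
p = (1 - C)^(K - (p - 2) - 1). Two facts, both established by simulation
during design, dictate where this law is applied:

* averaging across band bins and shrinking toward the identity both make
  the law strongly conservative (empirical rejection at the 5% level
  drops to 0.1-2%), and
* band-pass filtering *ahead* of the tapers makes the taper coefficients
  heteroscedastic (the taper bandwidth, (K+1)/2T, is comparable to the
  band width at these epoch lengths) and the law anticonservative
  (rejection near 30%).

The pipeline therefore reports the band-averaged regularized estimate,
but computes the p-value from the unregularized estimate at the bin
nearest the band centre of the *unfiltered* epoch, where the law
calibrates exactly. Significance flags come from Benjamini-Hochberg over
the pooled pairs-by-epochs family at q = 0.05. A degrees-of-freedom guard
requires 2K > 2(p - 2) + 2.

**Per-epoch bias and the jackknife.** With only K = 6 tapers the raw
per-epoch estimate is biased upward at low coupling (null mean
1/(K - p + 2) = 0.25) and compressed at high coupling, which attenuates
*differences* between conditions. Each record therefore carries a second
estimate, debiased by the leave-one-taper-out jackknife. The raw estimate
stays in [0, 1] and is what `estimate` reports; the jackknifed value can
leave [0, 1] under noise and is used where differences matter - the
lagged event regression uses it by default.

**Stationary (pooled) analyses** - the connectivity graph and oracle
comparisons - average epoch spectral matrices before inversion, which
removes the small-sample bias at rate 1/(K x epochs). For oracle
validation against a known VAR(1) system we pool with 2-s epochs and no
shrinkage: at the band's native epoch length the taper smoothing
bandwidth mixes frequencies with different true coherence and biases the
comparison by up to ~0.08, while 2-s epochs bring the worst pair within
~0.04. The VAR(1) generator (a three-channel chain X -> Z -> Y, diagonal
AR 0.5, chain coefficient 0.8) is provided solely as this oracle: its
closed-form spectral matrix `H Sigma H*` yields exact partial coherences,
including an exactly zero direct X-Y link that remains marginally
coherent.

## Event-locked inference

`lagged_event_regression()` regresses epoch-wise estimates on lag
indicators: the epoch containing an event start is lag 0, with three
epochs either side; all epochs more than three epochs from every event
form the baseline reference, so coefficients are changes from baseline.
Events without full lag context are dropped and counted. Epoch membership
uses a relative tolerance of 1e-6 epoch lengths so events nominally on an
epoch boundary open the epoch rather than close it. The same machinery
serves exploration bouts and sleep odor introductions.

The baseline connectivity graph pools still epochs (no overlap with any
moving 2-s EMG bin), computes pooled partial coherences and p-values with
K x epochs degrees of freedom, and draws an edge when the estimate
exceeds 0.15, solid when additionally p < 0.05. The rule itself is a pure
function (`graph_edge_rule()`), property-tested on a grid.

The movement confound check fits
`sniff_rate ~ emg_rms + (1 | animal_id)` with lmer (Satterthwaite
p-values via lmerTest), reports the fixed coefficient scaled by
SD(emg)/SD(sniff) as a correlation, and degrades to ordinary least
squares with a warning for a single animal. It is run on all bins and on
the still/moving subsets.

## The synthetic-session generator

The generator exists so that every estimator can be checked against exact
ground truth. It emulates:

* *Respiration* as a phase oscillator with per-cycle Gaussian frequency
  jitter truncated at 3 SD, an asymmetric cycle (inhalation occupies the
  first 40% of the cycle, as a negative half-sine, so troughs are sharp
  and detection nontrivial), per-cycle amplitude jitter, state-dependent
  parameters (defaults: wake 7 Hz / SD 1.0 / amplitude 1.0; NREM 3.2 Hz /
  SD 0.15 / amplitude 0.6; REM 3.1 Hz with doubled NREM jitter and
  amplitude jitter 0.15), and a configurable frequency increment inside
  exploration bouts. Truth carries the exact per-sample frequency and
  inhalation times (phase crossings, linearly interpolated).
* *EEG* as a per-band sum of a shared component, an independent
  band-limited noise of identical spectrum, and a broadband AR(1)
  background, with state-dependent band gains (delta up in NREM, theta up
  in REM) so the vigilance scorer has signal to work with. Two coupling
  mechanisms exist: a respiration-locked carrier (the respiration
  channel's in-band Fourier phases with flattened magnitude) for
  Resp-to-EEG coupling, and a shared flat band component between the two
  EEG channels (`eeg1_eeg2`). Mixing weights follow from the target
  coherence in closed form - `w^2/(w^2 + 1 + s_bb)` for the carrier
  route - and the implied coherences are exported in the truth.
* *EMG* as broadband noise with state-dependent tone (wake 3x, REM 0.3x
  the NREM level) and a burst gain (default 10x) inside movement
  intervals.
* *Trajectories* as smooth nose paths that cross the 2-cm bout perimeter
  exactly at planned bout boundaries, with centre and tail points trailing
  the nose, so the bout detector can be validated to frame precision.
* *Sleep-odor trials* with the full window layout, a respiration step at
  odor time, and a gap mask covering everything outside the one-minute
  sensor window.

What it does **not** emulate, and what that means for the tests: there is
no 1/f cortical background beyond AR(1), no volume conduction, no
movement artefacts in the respiration channel, and - importantly - a
narrowband sniff line cannot carry an arbitrary band-averaged coherence
through short locally-stationary epochs: the taper smoothing bandwidth
spans bins where the line has no power, so Resp-EEG band coherence
saturates below its nominal target. Quantitative coupling-recovery tests
therefore use the `eeg1_eeg2` route, whose components are flat within the
band; Resp-EEG coupling is exercised qualitatively (zero vs nonzero,
direction of change). Passing tests demonstrate estimator correctness
under these idealized conditions, not robustness to every property of
real recordings.

Determinism: one global seed feeds per-component streams (respiration,
EEG, EMG, tracking) derived by hashing the component name, so each
component is individually reproducible and sessions written twice are
byte-identical.

## Benchmark problem sizes

The validation suite sizes its simulations as follows: oracle equivalence
on a 10-minute VAR(1) record; null calibration over 5000 epochs and 1000
FDR replicates; chirp tracking over 2-13 Hz sweeps; bout-frequency
recovery over 50 trials; event-locked coupling recovery at 100 events
with baseline coupling 0.7 stepping to 0.9 during bouts (per-epoch
coherence estimates have sampling variance proportional to (1 - C)^2, so
the design resolves a +0.2 change with adequate precision at strong
baseline coupling, while a mid-range baseline would leave the check
noise-limited); mixed-model recovery at 2000 bins across 4 synthetic
animals; vigilance scoring over 10 minutes of 30-s state blocks with
balanced composition.

## Known limitations

* The vigilance scorer is a rule-based surrogate for semi-automated
  scoring with manual verification; it is validated only against
  synthetic truth, and its relative thresholds assume mixed-state
  sessions.
* Partial-coherence levels between a narrowband respiration signal and
  broadband EEG depend on the epoch length and taper count; absolute
  levels are not comparable across bands.
* The null p-value law assumes independent Gaussian epochs; strong
  autocorrelation of coupling across epochs would make the FDR family
  effectively smaller than pairs x epochs.
* EDF import assumes a single sampling rate across channels and ignores
  EDF+ annotations.
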