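# sniffsync

Respiration is more than gas exchange: in mice, sniffing is an active
sampling behaviour, and respiration-entrained activity is increasingly
seen as a global brain rhythm. Studying that link in freely moving
animals requires synchronized respiration (here: wireless thoracic
pressure, where inhalation is a negative deflection), EEG, EMG and video
tracking - and an analysis chain that can say how strongly breathing and
specific cortical rhythms are directly coupled, moment by moment, while
everything else (muscle activity, the other EEG lead) is controlled for.

sniffsync implements that chain as a tested R package, aimed at
neurophysiologists working with multichannel sleep/behaviour recordings:

* **Respiration metrics** - rolling dominant sniff frequency from a 1-s
  autocorrelation window shifted by 50 ms; inhalation-peak (trough)
  detection; flow-vs-thoracic sensor agreement (relative error, peak
  lags); bout-aligned frequency trials; intersniff-interval statistics
  per vigilance state.
* **Behaviour** - exploration-bout detection from a 2-cm nose perimeter,
  centre-point running velocity, EMG-RMS movement classification (2-s
  sliding bins, animal-relative threshold), and the
  frequency-versus-velocity cross-check.
* **Vigilance states** - rule-based wake/NREM/REM scoring in 5-s epochs
  from delta (1-4 Hz) and theta (4-10 Hz) power and EMG tone, plus
  sleep-odor trial bookkeeping (sensor-on and odor windows, state
  transition outcomes, paired pre/post comparisons).
* **Evolving partial coherence** - the spectral core. Each band (delta
  0.5-4, theta 4-8, alpha 8-12, beta 12-30 Hz) is cut into
  locally-stationary epochs holding ~5 cycles (2.22 / 0.83 / 0.5 /
  0.25 s); each epoch's spectral matrix S(f) is estimated with K = 1.5p
  = 6 orthonormal sine tapers, shrunk toward the scaled identity, and
  inverted: partial coherence between channels j and k is
  |G_jk|² / (G_jj G_kk) with G = S⁻¹, band-averaged, with null p-values
  p = (1-C)^(K-(p-2)-1) and Benjamini-Hochberg FDR over all pairs and
  epochs. Event-locked changes are estimated by regressing the epoch
  series on ±3 lag indicators around bout starts; baseline connectivity
  graphs pool still epochs and draw an edge when the estimate exceeds
  0.15 (solid when p < 0.05); a mixed model
  `sniff_rate ~ emg_rms + (1|animal)` checks the movement confound.
* **A synthetic-session generator** with exported ground truth - state-
  and bout-dependent respiration, band-coupled EEG, burst EMG, arena
  trajectories, sleep-odor layouts - so every estimator in the package
  is validated by parameter recovery, plus a VAR(1) oracle with a
  closed-form spectrum for the partial-coherence estimators.

## Worked example

Simulate a two-minute open-arena session with two 4-s exploration bouts,
a +5 Hz sniff increment during bouts, and theta-band EEG1-EEG2 coupling
of 0.5, then run the main analyses:

```r
library(sniffsync)
s <- generate_session(list(duration = 120,
                           approach_plan = data.frame(time = c(30, 70),
                                                      dwell = c(4, 4)),
                           couplings = list(theta = list(eeg1_eeg2 = 0.5)),
                           bout_increment = 5),
                      seed = 42)
s$record
#> <signal_record> 4 channels [EEG1, EEG2, EMG, Resp], 48000 samples @ 400 Hz (120.0 s)

freq <- estimate_resp_frequency(channel(s$record, "Resp"), 400)
tr <- extract_bout_trials(freq, s$events)
mean(tr$delta_frequency)
#> [1] 4.630516

pc <- evolving_pcoh(s$record, "theta")
summary(pc)
#>        pair mean_estimate n_significant
#> 1 EEG1-EEG2     0.4982696             1
#> 2 EEG1-Resp     0.1822263             0
#> 3 EEG2-Resp     0.2314538             0

mt <- classify_movement(channel(s$record, "EMG"), 400)
build_connectivity_graph(s$record, "theta", mt)
#> <connectivity_graph> band theta, 126 still epochs
#>   EEG1-EEG2  weight 0.447  solid (p < 0.05)
```

Reading the output: the injected +5 Hz bout sniff increase is recovered
at +4.6 Hz (1-s windows straddling bout onset absorb the rest); the
per-epoch theta partial coherence of the coupled pair averages 0.498
against a configured 0.5, while the uncoupled Resp pairs sit near the
small-sample noise floor; pooling the 126 still epochs, only the coupled
pair crosses the edge rule (weight > 0.15, p < 0.05). Single epochs are
rarely individually significant at K = 6 tapers - inference pools epochs,
as the graph does.

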