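# neuroload

Four-level mental workload detection from hybrid EEG–fNIRS recordings.

Operators of complex human–machine systems (aviation, driving, process
control) fail when their mental workload leaves the range they can
sustain, so passive workload monitors pair a graded multitask battery
(MATB: system monitoring, compensatory tracking, resource management)
with physiological recordings and ask a classifier which of four
difficulty levels (1, 3, 5, 7) the operator is working at. **neuroload**
implements that analysis end to end for 64-channel EEG (500 Hz) plus
two-site prefrontal fNIRS (50 Hz):

- **Synthetic session generator** — MATB-like sessions (4 blocks × four
  3-min difficulty segments) with difficulty-monotone band-power and
  hemodynamic modulation, ocular artifacts, pink/physiological noise, and
  retained ground truth for recovery testing. No public recordings
  accompany this task design, so the generator is first-class, tested
  code, not a fixture.
- **Preprocessing** — mastoid re-referencing, zero-phase 0.5–45 Hz
  Butterworth band-pass + 50 Hz notch, downsampling to 200 Hz,
  ocular-channel regression, fNIRS motion correction and 0.5 Hz low-pass,
  stimulus-anchored 3-s epoching on a shared EEG/fNIRS grid.
- **Feature battery** — Welch band powers in θ (3–8 Hz), α (8–13 Hz),
  β₁ (13–20 Hz), β₂ (20–30 Hz) per channel; seven channel-pair power
  differences; eleven statistical descriptors per chromophore trace
  (mean … crest/waveform/impulse/margin factors); neurovascular-coupling
  correlations. Assembled as only-EEG (276 full / 132 optimized-montage
  columns), only-fNIRS (44) and fused (180) sets, with per-subject
  |z| > 3 outlier removal.
- **Channel selection** — per-subject linear SVM-RFE top-100 band-power
  features, cross-subject importance weights (a feature's weight counts
  the subjects that selected it; a channel sums its four bands), an
  accuracy-vs-channel-count curve and plateau-based montage selection;
  the 26-channel optimized montage ships as `optimizedMontage()`.
- **Classification** — per-subject stratified 80/20 split with 5-fold
  cross-validated grid search: RBF SVM (8 costs × 8 gammas), decision
  tree (criterion × depth × min-split) and random forest (100/200/500
  trees); leakage-free standardization; min/mean/max/SD summaries across
  subjects and a two-way accuracy ~ featureSet × classifier ANOVA.
- **Statistical reports** — NASA-TLX / performance composite scores,
  per-channel ANOVA scalp maps with Benjamini–Hochberg FDR over all
  248 channel × band cells, high-minus-low band-power contrasts, and
  chromophore level effects.

## Worked example

A reduced 15-channel session (two blocks of four 30-s segments) keeps the
example fast; the defaults generate the full 64-channel, 3-min-segment
design.

```r
library(neuroload)

cfg <- sessionConfig(nBlocks = 2L, blockDuration = 30,
                     montage = c("Fp1", "AF3", "F3", "C1", "C2", "P3", "P4",
                                 "P7", "P8", "Pz", "O1", "O2", "Oz", "M1", "M2"),
                     seed = 7)
session <- generateSession(cfg, "S01")
session
#> RawSession S01
#>   EEG: 16 ch x 120000 samples @ 500 Hz (240 s)
#>   fNIRS: 4 traces x 12000 samples @ 50 Hz
#>   events: 8 segments, levels {1,3,5,7}

eegEpochs   <- preprocessEEG(session)      # reref, filter, 200 Hz, EOG, epochs
fnirsEpochs <- preprocessFNIRS(session)    # motion correct, low-pass, epochs

pairs <- data.frame(a = c("P8", "O2", "C2", "P4"), b = c("P7", "O1", "C1", "P3"))
sets <- assembleFeatureSets(eegFeatures(eegEpochs, pairs = pairs),
                            fnirsStatFeatures(fnirsEpochs),
                            nvcFeatures(eegEpochs, fnirsEpochs),
                            montageMode = "full")
sets$fused
#> FeatureTable: 80 epochs x 116 features
#>   subjects: S01
#>   per level: 1:20 3:20 5:20 7:20

fit <- splitAndTune(zscoreOutlierRemoval(sets$fused), "rf",
                    gridSearchSpec(rfTrees = c(100, 200)), seed = 1)
cat(sprintf("chosen ntree: %d | train acc: %.1f%% | test acc: %.1f%%\n",
            fit$params$ntree, fit$trainAccuracy, fit$testAccuracy))
#> chosen ntree: 100 | train acc: 100.0% | test acc: 62.5%

fx <- fnirsLevelEffects(fnirsEpochs)
print(subset(fx$levelMeans, site == "left"), row.names = FALSE)
#>  site chromophore level       mean
#>  left        O2Hb     1  0.6418917
#>  left        O2Hb     3  0.8379552
#>  left        O2Hb     5  0.9981918
#>  left        O2Hb     7  1.2292355
#>  left         HHb     1 -0.2538898
#>  left         HHb     3 -0.3258324
#>  left         HHb     5 -0.3868163
#>  left         HHb     7 -0.4736186
```

The 80 three-second epochs carry 116 features (4 bands × 13 scalp
channels + 4 pairs × 4 bands + 44 chromophore statistics + 4
neurovascular couplings). The random forest recognizes the four levels of
the held-out epochs well above 25 % chance at this reduced scale, and the
left-prefrontal level means show the configured physiology: O₂Hb rises
and HHb falls monotonically with difficulty. `runPipeline()` chains the
same stages for a multi-subject cohort and writes feature tables,
evaluation summaries, statistical reports and a checksummed run manifest.

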