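---
title: "Hybrid EEG-fNIRS mental workload detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid EEG-fNIRS mental workload detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroload)
```

## The problem

Operators of complex human-machine systems fail when their mental workload
leaves the range they can sustain. Passive detection of workload from
physiological signals therefore pairs a graded multitask battery (MATB:
system monitoring, compensatory tracking, resource management) with
multichannel EEG and prefrontal fNIRS, and asks a classifier to recognize
which of four difficulty levels (labeled 1, 3, 5, 7) the operator is
currently working at. **neuroload** implements that full analysis: signal
preprocessing, a hybrid feature battery, SVM-RFE channel ranking,
grid-searched classification of unimodal and fused feature sets, and the
statistical reports that document the physiology behind the features.

Because no public recordings accompany this task design, the package ships
a first-class synthetic session generator whose statistical structure is
the structure the analysis assumes. Every stage is tested against the
generator's retained ground truth.

## The synthetic session model

A session (`generateSession()`) consists of `nBlocks` blocks, each
containing one 3-minute task segment per difficulty level in a
subject-specific random order — the default 4 blocks x 4 levels x 180 s
give 16 segments and, at the default non-overlapping 3-s epoching, 240
epochs per level. Difficulty is mapped to $g(\ell) \in \{0, 1/3, 2/3, 1\}$
over the level range.

**EEG.** Each scalp channel is a sum over the four workload bands —
$\theta$ (3–8 Hz), $\alpha$ (8–13 Hz), $\beta_1$ (13–20 Hz),
$\beta_2$ (20–30 Hz) — of sinusoids with, per 3-s cell, a random in-band
frequency, random phase and lognormal amplitude jitter, plus pink
($1/f$) background noise. The band amplitude on *modulated* channels is
$A_b \,(1 + e \cdot s_b \cdot g(\ell))$ with effect size $e$
(`effectSize`, default 1) and band slope $s_b$: by default frontal
$\theta$ rises ($s=+0.5$), parieto-occipital $\alpha$ falls ($-0.4$) and
parieto-occipital $\beta_1/\beta_2$ rise ($+0.5$) with difficulty. This is
the simplest model whose Welch band powers are analytically controllable:
with `noiseSd = 0` the per-level band power is exactly
$A_b^2(1 + e s_b g)^2 / 2$, strictly monotone in difficulty. Blink-like
ocular transients (sharp rise, 150-ms exponential decay, ~0.25/s) are
mixed into the ocular channel (weight 1) and frontal rows (0.4 on Fp, 0.25
on AF, 0.12 on F), with the artifact trace and mixing weights retained in
`groundTruth()` so artifact-removal efficacy is measurable.

**fNIRS.** Each (site, chromophore) trace holds a per-segment
concentration plateau, linear in $g(\ell)$ — O2Hb $0.5 + 0.8\,e\,g$,
HHb $-0.2 - 0.3\,e\,g$ µmol/L, right site scaled by 0.9 — approached
through a smooth gamma-CDF rise (shape 4, rate 0.5, most of the
transition inside 15 s; the exact kernel is a configuration choice since
no published shape constrains it). Mayer-wave (0.1 Hz) and respiratory
(0.3 Hz) oscillations and white sensor noise are added. The session starts
on the first segment's plateau, so a zero effect size produces genuinely
exchangeable levels — an earlier design that rose from zero at session
start biased whichever level came first and broke the null calibration.

**Behavior.** One record per (block, level): six NASA-TLX dimensions with
expected value $20 + 55\,e\,g$ (0–100 scale) and six performance
indicators (monitoring response time and accuracy, tracking X/Y
deviations, tank A/B deviations) whose expected quality degrades linearly
with $g$. All stochastic scales are multiples of `noiseSd`.

**What the generator does not emulate.** No volume conduction or
leadfield (channels are independent up to the shared ocular source), no
non-stationarity beyond the difficulty modulation, no cross-subject
amplitude variability beyond the seed, no task-evoked transients inside a
segment, and no optical-density stage — fNIRS is generated directly in
concentration units. Passing recovery tests therefore demonstrates that
the *analysis code* recovers what it assumes, not that the method will
attain any particular accuracy on human data.

## Preprocessing

The EEG chain is fixed: mastoid re-reference, band-pass + notch,
downsample, ocular removal, epoching.

* **Re-reference** subtracts the M1/M2 average from every scalp channel
  and drops the mastoids.
* **Filtering** is a 0.5–45 Hz Butterworth band-pass followed by a 50 Hz
  notch. The order (4) and notch Q (30, RBJ biquad) are package defaults,
  configurable. Both are applied forward-backward for zero phase; the
  implementation evaluates the difference equation through C-level
  recursive filtering with odd-reflection padding and matches the analytic
  two-pass magnitude response to four decimals in tests.
* **Downsampling** to 200 Hz applies a zero-phase anti-alias low-pass
  (order 8, corner at 80 % of the target Nyquist) and uniform Catmull-Rom
  cubic resampling; a 10 Hz sinusoid survives 500→200 Hz with < 0.1 %
  amplitude error. (A polyphase resampler we evaluated showed ~7 %
  passband ripple at this rate ratio, which is why the package uses its
  own resampler.)
* **Ocular removal** is deterministic reference-channel regression: the
  auxiliary ocular channel is regressed out of every scalp channel by
  least squares. ICA-based removal is the common alternative but needs a
  component-rejection rule that published descriptions rarely pin down;
  regression is reproducible and directly testable against the
  generator's mixing ground truth.
* **Epoching** cuts `length = 3` s windows every `stride` seconds from
  each segment's stimulus onset, labeling each window with the segment's
  level. The default stride is 3 s (non-overlapping). Published sample
  counts for this design (960 per level and subject) are four times the
  non-overlapping count, pointing at overlapping windows whose exact
  stride is not documented; the stride is therefore left configurable and
  the package default stays at the literal non-overlapping reading.

fNIRS preprocessing is motion correction, a 0.5 Hz zero-phase low-pass
(order 4) and the same epoch grid, so EEG and fNIRS epoch k cover the
same wall-clock window. Motion correction is robust derivative
correction: first differences beyond `thresh` robust SDs
(1.4826 × MAD) are replaced by the clean median difference and the trace
reintegrated, which repairs both spikes and persistent baseline steps.
The default threshold is 8: at 3 robust SDs about 0.3 % of clean Gaussian
samples are falsely flagged and the reintegration drift measurably
inflates the false-positive rate of the downstream level ANOVA, while
genuine artifacts (10 SD and larger) sit far above either threshold.

## The feature battery

* **EEG band powers** (`welchBandPower()`): Welch PSD with 1-s Hann
  segments at 50 % overlap on the 3-s/200 Hz epoch (5 averaged
  periodograms, 1 Hz bins), integrated over $[lo, hi)$ per band —
  `<channel>_<band>_psd`, 248 features for the 62-channel scalp montage.
  Tests pin the estimator to a brute-force single-taper periodogram
  within 5 % on noiseless sinusoids.
* **Pair differences**: power(a) − power(b) for the seven lateral and
  antero-posterior pairs P8–P7, O2–O1, C2–C1, P4–P3, Pz–O1, Pz–O2, O1–AF3,
  per band — 28 features.
* **fNIRS statistics**: eleven descriptors per (site, chromophore) trace:
  mean, SD, mean squared deviation from the mean (the "mean square error"
  of the battery — the biased variance; the name is kept as an alias),
  skewness, RMS, peak (max |x|), crest factor (peak/RMS), kurtosis,
  waveform factor (RMS / mean|x|), impulse factor (peak / mean|x|) and
  margin factor (peak / mean(√|x|)²) — the standard vibration-analysis
  forms; 44 features.
* **Neurovascular coupling** (`nvcFeatures()`): per site, the zero-lag
  Pearson correlation between each chromophore trace and the frontal EEG
  band-power time-course within the epoch — 4 features in [−1, 1]. The
  band-power time-course is computed on channel AF3 (the frontal site
  closest to the optodes), as the mean over the four bands in sliding
  0.5-s sub-windows stepped by 0.1 s and interpolated onto the fNIRS
  grid; channel, pooling, window and stride are configurable since only
  "frontal EEG band power" is specified by the design.

`assembleFeatureSets()` produces only-EEG (4m + 28 columns: 276 full, 132
for the 26-channel optimized montage), only-fNIRS (the 44 statistics —
the NVC features need EEG and would make the set non-unimodal) and the
fused set (optimized EEG + 44 + 4 = 180). `zscoreOutlierRemoval()`
z-scores every feature within subject and drops epochs containing any
|z| > 3. Whole epochs (rows) are dropped, not single cells, because
downstream sample counts are reported per dataset; note that with ~180
weakly dependent features this removes a substantial fraction of epochs
(roughly half at the defaults), which is the literal consequence of the
row-wise reading.

## Channel selection

Per subject, a linear-kernel SVM-RFE (`rfeTopFeatures()`) ranks the 248
per-channel band-power features, eliminating the lowest-|w| 10 % of the
remaining features per iteration until 100 remain. Feature weights are
squared linear weights summed over one-vs-one class pairs; the linear
kernel is used because elimination needs explicit feature weights, which
the RBF classifier of the final models does not provide. Pair-difference
features span two channels and are excluded from channel scoring. A
feature's cross-subject weight counts the subjects whose top-100 set
contains it; a channel's weight sums its four band features; ties break
by montage order so the report is order-invariant
(`aggregateImportance()`). `incrementalAccuracyCurve()` adds channels in
ranking order and `selectMontage()` picks the first count at which the
3-point moving average of the accuracy gain drops below 0.5 points
(configurable; with threshold ≤ 0 the argmax is used). The 26-channel
optimized montage (`optimizedMontage()`) — parieto-occipital sites plus
AF3, C1/C2 and temporo-parietal channels — ships as a packaged constant
for reproduction of the optimized configuration.

## Classification

One model per subject (`splitAndTune()`): stratified 80/20 split, 5-fold
cross-validated grid search on the training partition, refit of the best
combination, test accuracy on the held-out 20 %. Feature standardization
uses training-partition statistics only; a leakage canary in the test
suite corrupts the held-out rows and asserts the learned statistics do
not move. Grids: RBF SVM with cost {0.0001, 0.001, 0.01, 0.1, 1, 10, 20,
30} × gamma {0.1, 0.2, 0.25, 0.4, 0.8, 1.6, 3.2, 6.4}; decision tree with
criterion {entropy, gini} × max depth {10, 30, 60, 100} × min split {2,
5, 10, 15}; random forest with {100, 200, 500} trees. The tree learner is
rpart, whose hard depth limit is 30, so depths 60 and 100 clamp to 30 —
at these sample sizes depth 30 is never binding, so the clamped grid
points are equivalent models. Remaining hyperparameters stay at library
defaults. `evaluateAll()` crosses the three feature sets with the three
classifiers and summarizes per-subject test accuracies as min/mean/max/SD
(`summaryTable()`); `accuracyAnova()` runs the two-way
accuracy ~ featureSet × classifier ANOVA. Pooled-across-subjects modeling
is possible by concatenating feature tables, but per-subject modeling is
the default because the summary statistics are defined across subjects.

## Statistical reports

`compositeScores()` min-max normalizes each of the six TLX dimensions and
six performance indicators and averages them; performance components
where lower is better (response time, deviations) are negated before
normalization so the composite is a quality score — without that
sign-alignment a "performance" composite would mix directions and trend
nowhere. `levelAnova()` is a one-way ANOVA with all pairwise post hoc
t-tests, Benjamini-Hochberg adjusted by default (Bonferroni available via
`adjust`); the mixed published terminology ("Bonferroni-corrected ANOVA"
with FDR post hocs) is resolved as plain ANOVA + BH post hocs with the
Bonferroni switch. `scalpAnovaMap()` applies the level ANOVA per
(channel, band) and corrects all 62 × 4 = 248 raw p values as one BH
family — post hoc pairs form their own family per cell.
`bandContrastMap()` is the within-subject mean power difference between
the highest and lowest level, averaged across subjects.
`fnirsLevelEffects()` tests epoch-mean chromophore amplitudes across
levels and returns per-level mean time-courses.

## Numerical and testing choices

Degenerate inputs are defined, not fatal: zero-variance traces get
skewness/kurtosis 0, ratio descriptors of an all-zero trace are 0 (and
crest factor of a nonzero constant is exactly 1), constant series yield
NVC 0, constant features z-score to 0, subjects with fewer than two
epochs pass through the outlier filter with a message. Grid-search ties
resolve to the first combination in grid order; ranking ties resolve to
montage order. All randomness is seeded: a session is a pure function of
(seed, subject ID), and every classifier fit reseeds deterministically,
so reruns reproduce output checksums (`runPipeline()` records them in its
manifest).

The test suite and the acceptance script run on scaled-down cohorts —
sessions of one or two blocks with 30–90 s segments for unit tests, and
for the acceptance computations one to five subjects with 90–180 s
segments — sizes chosen so trends configured into the generator are
detectable while a full run stays inside a few minutes on one CPU. The
classification cohorts epoch with the overlapping 0.75-s stride that the
published per-level sample counts imply (roughly 240 windows per 180-s
segment): because the row-wise outlier rule preferentially removes epochs
of the extreme difficulty levels (their difficulty-monotone features sit
in the pooled z-score tails), non-overlapping epoching of a single block
can leave a class too small for stratified 5-fold tuning. Overlapping
windows share samples, so absolute accuracies on them are optimistic;
the fused-vs-unimodal comparison is unaffected since all three sets use
the same epochs. The
vignette's claims about accuracies, null rates and recovered channels are
exactly the quantities `scripts/acceptance.R` recomputes; nothing here is
asserted that the tests do not compute.

## Limitations

Synthetic recovery bounds what these results can claim: published
four-level accuracies from 20 human subjects (mean 76 % for the fused
random forest) are not reproducible without the recordings, and the
package does not attempt them. The generator's independence across
channels makes channel selection easier than on volume-conducted scalp
data; the NVC features carry no configured class signal (they are
near-null correlations on synthetic data) and are included for battery
completeness; and EDF import is out of scope — sessions are serialized
as delimited tables with a JSON manifest.
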