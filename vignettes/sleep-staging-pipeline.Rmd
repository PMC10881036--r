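---
title: "Staging fly sleep from multichannel LFP: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging fly sleep from multichannel LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`flysleeplfp` re-implements, as a tested pipeline over synthetic data, an
analysis strategy for long-term 16-channel local field potential (LFP)
recordings in behaving *Drosophila*: movement-based sleep segmentation,
polarity-reversal re-referencing, channel-by-frequency spectral features,
cluster-based permutation statistics, classifier-probability staging,
microbehavior (proboscis, antenna) event detection, and random-intercept
mixed-model comparisons. This vignette explains the models behind each
stage, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The measurement model

A linear 16-site probe (25 um spacing) inserted through the eye samples
LFPs from retina to central brain. Because insertion depth varies between
animals, the probe is anchored functionally: a square-wave visual stimulus
evokes deflections whose polarity flips between the optic lobe and the
central brain, and recordings are only comparable when that reversal falls
on channels 11-13. The reversal channel doubles as the reference: after
subtracting it from every other channel, 15 channels remain and any signal
common to all sites (heartbeat, body movement, drift) cancels. Channel
groups follow the anatomy: central 1-5, middle 6-10, peripheral 12-16
(original indices).

Sleep is defined behaviorally: five minutes or more without detected
movement. Each sleep bout is partitioned into temporal stages with
half-open intervals:

* presleep: the 2 min before immobility onset (the fly still moves),
* earlysleep: the first 2 min of the bout,
* latesleep: the last 2 min,
* midsleep: everything between earlysleep and latesleep,
* awake: all residual time.

A 300-s bout therefore has a 60-s midsleep. A presleep window truncated by
the recording edge (or by a preceding bout closer than 2 min) is flagged
`partial` and excluded from staging features; the windows used only for
classifier probing (minutes -4 to -2 before onset, and the 2 min after
offset) are labeled `pre2_probe`/`post2_probe`.

## The synthetic-data generator

No recordings ship with the package; every analysis is exercised on
sessions from `generate_session()`, which produces LFP, a movement trace
(or raw 64 x 48 grayscale frames), wide-format pose traces, and complete
ground truth. The LFP model is deliberately the simplest one that makes
every downstream contrast realizable and tunable:

* per channel, 1/f colored background noise (amplitude 0.35) plus
  band-limited Gaussian components with dB-calibrated gains;
* a common-mode component on all channels (slow 0.5-4.5 Hz drift plus a
  heartbeat-like 2.5-3.5 Hz band), kept below the 5-40 Hz analysis band so
  it exercises re-referencing without diluting the calibrated state
  contrast;
* a broadband 5-40 Hz component whose power is
  `wake_broadband_gain_db` (default 6 dB) higher in wake than in midsleep.
  The descent is gradual (`stage_broadband_frac`: wake 1, presleep 0.30,
  earlysleep 0.15, latesleep 0.10, midsleep 0), so the brain "falls
  asleep" during presleep, two minutes before the body stops moving, and
  early/late sleep sit between wake and midsleep. This is what makes the
  classifier-probability probe reproduce the qualitative pattern
  p(awake|awake) > p(awake|presleep) > p(awake|earlysleep) >
  p(awake|midsleep), with the minute -2:-1 probe below 0.5;
* a central-channel (1-3) 5-10 Hz component whose dB offset follows
  `stage_profile` (awake 0 > presleep -2 > earlysleep -4 >= latesleep
  -4.5 > midsleep -7). These offsets carry the stage identity that the
  five-class random forest must recover, which is why its importance map
  concentrates in channels 1-3 x 5-10 Hz;
* on peripheral channels (12-16), the 10-30 Hz share of the broadband
  component is modulated symmetrically during sleep: day bouts up and
  night bouts down by `daynight_peripheral_delta_db / 2` (default delta
  3 dB). The symmetric split keeps pooled sleep power calibrated against
  the wake gain while giving the day/night classifier a clean target. A
  bout keeps the day flag of its onset, matching the labeling convention
  downstream;
* PE-locked components: middle-channel broadband is attenuated by 3 dB
  around wake PEs, and a central 32-40 Hz component (+3 dB scale) turns on
  around sleep PEs.

Bout structure alternates exponential wake (minimum 240 s) with lognormal
sleep (`mu = log 550`, `sigma = 0.45`, truncated at 315 s so every
generated bout satisfies the 5-min criterion); the rate is set so cycle
length is `3600 / sleep_bout_rate`. Night bouts get `+0.4` on the log-mean
so night sleep is longer, mirroring the day/night bout-duration asymmetry
of healthy flies. Movement is emitted in whole-second blocks
(`move_prob_wake = 0.55`, multiplied by `crepuscular_peaks` at dawn 7-9
a.m. and dusk 7-9 p.m.), with forced movement in the seconds flanking each
bout boundary — immobility onset is *defined* by the last movement — and
rare 2-frame blips during stillness that the pruning step removes.

PE bursts are placed by context (midsleep 0.6, other sleep 0.05, wake 0.15
bursts/min), are single with probability 0.33, otherwise have 2 + Poisson
(1.8) events with lognormal inter-PE intervals (mean 1.5 s, sdlog 0.12,
95th percentile ~1.8 s). Distinct bursts are kept >= 12 s apart so the
10-s burst-merging rule downstream can never fuse two generated bursts.
In the pose traces a PE is a 0.4-s raised-cosine displacement of the
proboscis away from the eye (12 px) during which the tracked likelihood
sags to ~0.55; separately, occlusions (~1/10 min, ~1 s) collapse
likelihood to ~0.3 and scramble the coordinates, and 15% of PE events are
occluded — this forces the detection pipeline to use the
likelihood-threshold augmentation and not just the frame classifier.
Antennal tips oscillate at 1 Hz (8 deg amplitude) during "periodic"
30-s segments covering 50% of sleep and 10% of wake, on top of 2 deg
white noise, with a slow whole-head wobble that the angle computation must
correct away.

What the generator does **not** emulate: spike waveforms, realistic
artifact morphology (the common mode is generic), photorealistic video
(the blob exercises the image operators, nothing more), pose-estimation
network behavior (likelihood dips are scripted, not learned), or
duration-linked spectral differences between short and long midsleep —
the last is intentional, so the short/long midsleep classifier lands near
chance, the same null outcome the analysis is designed to expose. Passing
tests therefore show that the pipeline recovers what it is pointed at
under its own assumptions; they are not evidence about real recordings.

## Preprocessing and spectra

Raw LFP is resampled to 250 Hz (anti-aliased FIR plus interpolation),
bandpassed 0.5-40 Hz with a hamming windowed-sinc FIR and notched at 50 Hz
(width 2 Hz). The two kernels are cascaded and applied once in the
frequency domain with their linear phase removed, i.e. exactly zero-phase
with the designed magnitude applied a single time; a 10-Hz probe sine
passes with amplitude error under 1% and zero lag. Transition bandwidths
are 0.5 Hz (low edge) and 10 Hz (high edge). Hourly segments are joined
with a short linear seam.

Epochs of 60 s (sleep/wake and staging) or 1 s (PE contexts) tile each
labeled interval from its onset, dropping the remainder; a condition is
retained per fly only with >= 10 (60-s) or >= 50 (1-s) epochs. Welch
spectra use 2-s hann windows at 50% overlap (a 1-s epoch is a single
window), are converted to dB (10 log10), and are interpolated onto a fixed
grid of 145 bins spanning 5-40 Hz. The grid is pinned to the printed
15 x 145 feature dimension rather than to any particular estimator
window; the integral of the estimated density tracks time-domain variance
within 5%.

## Cluster-based permutation testing

Per-fly mean difference maps (condition A - condition B, dB) feed a
one-sample t test per (channel, frequency) cell. Cells with |t| above the
two-sided alpha = 0.05 threshold (df = n - 1) are joined by 4-connectivity
on the channel x frequency lattice — probe neighbors and adjacent bins;
positive and negative cells cluster separately — and each cluster's mass
is the sum of |t|. The null flips the sign of whole fly rows: all 2^n
flips for n <= 14 (the identity included), otherwise 4096 random flips.
Cluster p is the fraction of null maximum masses at or above the observed
mass; ties count (conservative), with a 1e-9 tolerance so the identity
flip always ties its own cluster regardless of floating-point summation
order. Sign flips leave per-cell sums of squares unchanged, so the
permuted t maps are computed from flipped means alone — this is what
makes full enumeration cheap. Effect sizes accompany the test as Cohen's
d: across-fly mean difference over across-fly SD, per cell.

## Classifier procedures

All classifier recipes share: stratified 80/20 splits, per-feature
standardization fit on training rows only, and five independently seeded
iterations (seeds `seed + 0..4`).

The **probability stager** trains a linear-kernel SVM with Platt-calibrated
probabilities on awake vs midsleep only, after random downsampling of the
majority class. Epochs from stages never seen in training (presleep,
earlysleep, latesleep, minute-resolved probes) are then scored with each
iteration's model, giving the awake-class probability per minute relative
to bout onset/offset. The **midsleep-duration stager** reuses the recipe
with short (< 14 min) vs long (>= 14 min) midsleep; the boundary point
itself goes to "long".

The **multiclass random forest** balances classes with SMOTE (k = 5
nearest within-class neighbors, convex interpolation). SMOTE runs before
the split by default, which reproduces the reference recipe but leaks
synthetic neighbors of test rows into training; `smote_before_split =
FALSE` gives the leakage-safe variant, and the test suite documents that
the two differ. Hyperparameters come from a randomized-then-grid search by
out-of-bag error over a small documented grid (trees {200, 500}, depth
{unlimited, 10, 20}, mtry {sqrt(p), 0.1 p}), with ties resolved toward
the cheaper setting; tuning happens once, on the first iteration's
training data, and is reused across iterations. Metrics follow the
textbook definitions (recall TP/(TP+FN), precision TP/(TP+FP), F1 the
harmonic mean, rank-based AUC, row-normalized confusion matrix).

**Permutation feature importance** is the held-out kind: shuffle one
feature column in the test rows, measure the score drop, repeat 5 times
per split, average over splits. Two numerical choices matter. First, the
score is the mean predicted probability of the true class rather than hard
accuracy: with 2175 highly redundant features a single shuffled column
almost never flips a majority vote, so the accuracy-based importance is
identically zero while the soft score degrades smoothly. Second, the
importance is evaluated on a small stratified subsample of held-out rows
(6 per class) with predictions batched over feature chunks — the map
needs rank structure, not precise values, and this keeps the
2175-feature x 25-shuffle loop affordable.

## Microbehavior detection

Pose traces are filtered twice per body part: a 0.1-Hz Butterworth
low-pass (applied about the trace mean, since at that cutoff filtfilt
otherwise drags long edge transients across short traces) for the posture
baseline, and a 5-sample moving average. The PE frame classifier is an
RBF-kernel SVM over deviations from baseline, first differences,
likelihoods and the likelihood-weighted proboscis-eye distance, with a
70/30 frame split. Negatives are subsampled for training, except that
every "hard" negative (likelihood below 0.8 — occlusions look like PEs
to naive features) is kept. Candidates are classifier positives plus the
augmentation rule: brief likelihood dips (< 0.8 s; a PE-driven sag is much
shorter than an occlusion) with classifier support within 0.25 s.
Candidate runs closer than 0.2 s merge, runs under 3 frames are discarded
as blips, and the trace edges (1.5 s) are excluded as filter warm-up.

Event peaks are the maximum of the *smoothed, unweighted* proboscis-eye
distance, so a likelihood collapse cannot displace the peak. Events
within 10 s share a burst; a burst of one is "single". An event is
periodic iff it follows its predecessor by less than 6 s, and the first
event of a burst inherits its successor's gap (the rule as stated covers
only successors; this extension is symmetric and affects only burst
heads). Event-level accuracy against ground truth is matches divided by
the larger of the truth and detected counts, so both misses and spurious
detections count against it.

Antennal angles are computed per antenna as the tip's atan2 angle about
its base, rotated into the head frame defined by the left-base to
right-base axis (the left side mirrored so both antennae share one sign
convention); whole-head rotation leaves the corrected angle unchanged.
Periodicity per 30-s segment uses a Welch-averaged spectrum (quarter-
segment windows): a segment is periodic iff the dominant peak in
0.33-5 Hz is at least 4x the median spectral power. The Welch averaging
is what lets the 4x-median rule pass null calibration — on a raw
periodogram the maximum of ~150 exponential bins exceeds 4x the median
almost surely, and the white-noise false-positive rate would be near 1
instead of under 5%.

The behavioral-rig variant (`resting_pe_detection()`) measures distance
from the median (resting) position, finds peaks, and excludes artifacts:
peaks above 40 px, single-frame spikes (no neighbor above half height),
and rises above 5 px/frame; a threshold-crossing alternative reports event
spans with duration and median angle.

## Mixed-model harness

All models are random-intercept linear mixed models, response ~ fixed
factors + (1 | fly), fit by maximum likelihood (not REML) so
likelihood-ratio tests on fixed effects are valid. The harness covers the
model families used across the analyses: null vs single-factor (antennal
and proboscis periodicity by epoch, movement by crepuscular period, by
recorded hour, PE counts by time label) and the null/epoch/channel/
epoch-x-channel family for spectral power. The winner is the model with
the higher log-likelihood *and* a likelihood-ratio p < 0.05; otherwise the
simpler model. Main-effect tests default to marginality-respecting
per-term likelihood-ratio chi-squares (interaction tested against the
additive model, each main effect by dropping it from the additive model),
which makes the single-factor case agree exactly with the LRT against the
null; a Satterthwaite F table is available as `type = "F"`. Pairwise post
hocs use estimated marginal means with Tukey adjustment and Satterthwaite
degrees of freedom. Binary periodicity indicators are modeled as linear
probability responses for harness simplicity; the logistic alternative is
a one-line change at the user level and is not wired in by default.

## Problem sizes and determinism

Every stochastic step takes an explicit seed: session = config seed,
cohort member i = cohort seed + i, classifier iteration j = seed + j - 1.
The packaged analyses and tests run on desk-scale cohorts chosen to keep
a full run in minutes on one core: 13 flies x 1 h for the wake/sleep
cluster contrast and the five-class forest, 6 flies x 2 h spanning
lights-off for the day/night forest, 10 flies x 45 min of pose for PE
detection, and a single 3-h session for the generator's spectral
calibration checks. The calibration check disables the day/night
peripheral modulation, which by design shifts day and night sleep power
by +-delta/2 about the calibrated level.

## Known limitations

* The spectral feature grid interpolates the Welch estimate; absolute dB
  values depend on the window convention, and only within-pipeline
  comparisons are meaningful.
* SMOTE-before-split is the default for fidelity to the reference recipe
  despite its leakage; metrics from it are optimistic.
* The PE frame classifier is trained per fly on ground-truth example
  frames; with real pose estimates the annotation step is manual and
  per-fly thresholds ("custom defined threshold per fly") would need
  tuning.
* The generator's effects are additive band-limited components; real LFP
  nonstationarities (movement artifacts, electrode drift within a band)
  are not represented, so classifier scores here are upper bounds on what
  identical recipes achieve on real data.
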