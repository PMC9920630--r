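---
title: "Recognising emotions from wearable electrodermal activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising emotions from wearable electrodermal activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edamotion)
```

## The problem

A wrist wearable with a galvanic skin response (GSR) sensor logs skin
resistance (ohms) with millisecond timestamps. Sweat-gland activity, driven
by sympathetic arousal, lowers that resistance, so its reciprocal — skin
conductance, or electrodermal activity (EDA) — carries an emotional
signal. `edamotion` turns such logs into emotion predictions on Russell's
circumplex: the four quadrants of the valence × arousal plane, **Happy**
(+, +), **Sad** (−, −), **Aggressive** (−, +) and **Relaxed** (+, −).

The pipeline has five stages: signal conditioning, skin conductance
response (SCR) detection, feature extraction, feature selection, and
classification, plus a streaming mode that classifies each 30 s window of
a live trace. Because the listening study that motivates the design
published no recordings, the package ships a synthetic experiment
generator that makes every stage testable end to end, with known ground
truth.

## Signal conditioning

1. **Conversion.** Conductance in microsiemens is `10^6 / resistance(ohm)`
   — the physical reciprocal; no calibration constants are assumed. Device
   timestamps are close to, but not exactly, uniform, so samples are
   linearly interpolated onto a uniform grid at the device's nominal rate
   (8 Hz by default; the true rate is a free parameter of the hardware).
2. **Downsampling to 2 Hz.** Each output sample is the mean of its source
   block. Averaging rather than decimation was chosen deliberately: EDA
   information lives well below 1 Hz, and block means act as an
   anti-aliasing filter, so the reduction loses essentially nothing while
   plain decimation would fold sensor noise into the band of interest.
3. **Artifact removal.** A running median (default window 5 samples =
   2.5 s at 2 Hz, reflect-padded edges) suppresses electrode-motion
   spikes. The width is a compromise: long enough to span a motion
   transient, short enough not to flatten a 3 s SCR rise.

## Tonic/phasic decomposition and SCR detection

The conductance trace is modelled as a slow tonic level (skin conductance
level) plus fast phasic fluctuations (the SCRs). The tonic estimate is a
centred moving average (default 10 s, reflect-padded); the phasic
component is the residual, so the decomposition reconstructs the input
exactly. A transparent linear smoother was preferred over
convex-optimisation decompositions because it is reproducible to the last
bit, trivially testable (the moving average of a line is the line), and
fast enough for 30 s streaming windows; the detector consumes only the
phasic series, so a different decomposition can be substituted upstream.

A physiologically relevant change must sustain a slope of at least
**0.01 µS/s** for at least **3 s**; rising runs are peaks, falling runs
offsets. Two operational choices matter here, and both were driven by
measurement on generated data with known ground truth:

* **Slopes are taken on a lightly smoothed phasic series** (3-sample
  centred moving average; `slopeSmooth = 1` restores raw differences). At
  2 Hz, sensor noise of realistic size (sd 0.005 µS) makes single
  first differences cross the ±0.01 µS/s threshold erratically.
* **Runs are qualified by their mean slope**, i.e. a maximal constant-sign
  monotone excursion counts if `|total change| / duration ≥ 0.01 µS/s`
  and `duration ≥ 3 s` — rather than requiring every instantaneous slope
  to clear the threshold. With per-sample thresholding, one noisy
  sub-threshold instant splits a genuine 4 s rise into fragments that each
  fail the duration rule; injection-recovery on low-noise synthetic
  segments measured only 62% of known SCRs recovered under per-sample
  thresholding, against 97% (with 0.08 false peaks/min) under mean-slope
  qualification. The two published thresholds are applied unchanged; only
  the reading of "a change with this slope and duration" differs.

Event **amplitude** is the absolute phasic change across the run in µS.
The feature table's amplitude descriptors are sometimes described as
being "in seconds" — a unit that contradicts the word amplitude; we treat
that as a slip and default to µS, but `amplitudeUnits = "s"` preserves the
literal reading (run duration) for comparability.

## Features

Fifteen descriptors per labelled segment. Nine statistical, computed on
the filtered 2 Hz signal: Mean, Median, Std (population convention),
Max, Min, Kurtosis (excess), Skewness (standardised third moment; both
moments are defined as 0 for zero-variance input), AUC (trapezoidal area
divided by duration — mean µS per second), and PSD, operationalised as the
median of a Welch power-spectral-density estimate (Hann window, 64-sample
segments, 50% overlap, per-segment mean removal). Six event-related,
computed from the detected SCRs: MeanPA/MaxPA over peak amplitudes,
MeanOA/MaxOA over offset amplitudes (0 when no such event), and PPS/OPS,
the peak and offset counts divided by the window duration in seconds.

Features are min–max normalised per column. By default inside
cross-validation the scaler is refit on each training fold and applied to
the held-out fold (min–max normalisation is invariant to positive affine
maps, so refitting on an already-normalised table is equivalent to
refitting on raw features); fitting one global scaler before modelling —
as whole-dataset pipelines often do — leaks fold information and is
available via `paperFaithful`-style arguments but is not the default.
The fitted scaler is stored with the table so streaming windows are
transformed consistently at prediction time.

## Feature selection

Three univariate tests each produce a full ordering of the fifteen
features: the chi-square feature-screening statistic (on class-summed
non-negative feature mass — this is why selection runs on the normalised
table), the one-way ANOVA F statistic, and mutual information with the
label, estimated by a k-nearest-neighbour estimator (k = 3) for a
continuous feature against a discrete label, with a tiny seeded jitter
for tie-breaking. The orderings are combined by **Borda rank-sum voting**:
each test contributes its positional rank, features sort by ascending rank
sum, ties break by the ANOVA-F rank and then name. Borda is the simplest
aggregation consistent with "order, then vote", and is invariant to the
order the rankings are supplied in. One-vs-rest label recodings give each
quadrant its own ranking, since a feature can matter for one quadrant and
not another.

## Classifiers and model selection

Two architectures: a single **four-class** model, or **four one-vs-rest
binary** models (one per quadrant), each emitting a probability; a
prediction is four (flag, probability) pairs in Happy, Sad, Aggressive,
Relaxed order with `flag = probability ≥ threshold` (default 0.5 — the
only threshold consistent with the worked output examples the system
documents). Five algorithm families are wrapped behind one
fit/predict-probabilities interface: k-nearest neighbours (in-package,
because the full per-class vote-fraction vector is needed), random forest
(`randomForest`), multi-layer perceptron (`nnet`), linear SVC (`e1071`,
decision scores mapped through a logistic and renormalised — margin
classifiers must still honour the probability contract), and gradient
boosting (`xgboost`, single-threaded for determinism).

Model selection is a randomised search over sampled hyperparameter
configurations (default 50 per algorithm) crossed with feature-count
prefixes {5, 8, 10, 12, 15} of the relevant ranking, scored by mean F1
under **repeated stratified 5-fold cross-validation** (default 10
repeats; the repeat count is unspecified in the source procedure, 10 is
the conventional choice). F1 is the selection metric because the
one-vs-rest tasks are imbalanced (25% positive). All randomness — fold
assignment, hyperparameter draws, stochastic fits — flows from one seed.

## The synthetic experiment

The generator emulates a listening study: 32 participants, one session
each, following a nine-song protocol (an opening relaxation song, then
two songs per quadrant, 260 s per song, 15 s silent pauses — 2460 s, 41
minutes), logged at 8 Hz. Per song, EDA is simulated as
`tonic baseline + random-walk drift + Σ SCR kernels + Gaussian noise`,
with SCRs arriving as a Poisson process (log-normal amplitudes, linear
rise, exponential decay) and the trace emitted in the device's raw format
via `R = 10^6 / EDA`. Ground-truth onsets are recorded alongside.

Quadrant profiles encode the physiological premise that EDA tracks
*arousal*: high-arousal quadrants (Happy, Aggressive) get 6 SCRs/min with
median amplitude 0.3 µS; low-arousal quadrants (Sad, Relaxed) get
1.5/min at 0.1 µS. Valence, which EDA does not genuinely encode, is
expressed as a mild tonic-baseline separation (Happy 6, Aggressive 4,
Relaxed 3, Sad 2 µS) — a modelling convenience that makes all four
quadrants learnable, flagged clearly as such: passing classifiers on this
corpus demonstrate that the pipeline can learn what its inputs contain,
not that real EDA separates valence. SCR rise times (3.5 s high-arousal,
3.2 s low-arousal) are chosen so a median event is detectable under the
3 s / 0.01 µS/s rules — a documented coupling between generator and
detector defaults, enforced by a validity check on the profile class.
Seven sessions are corrupted, cycling through truncation, timestamp
scrambling, out-of-range bursts and sample-dropout gaps, so every
validation reason code (`TRUNCATED`, `NONMONOTONE_TIME`, `OUT_OF_RANGE`,
`GAP`) occurs in the default corpus and the validation stage discards
exactly 7 of 32 sessions, leaving 25 × 8 = 200 labelled segments, 50 per
quadrant.

Validation rules (coverage ≥ 90% of the protocol duration, strictly
increasing timestamps, resistance within 10 kΩ–10 MΩ, no gap over 5 s)
are the package's operationalisation of "discard sessions with errors or
incomplete data"; the source procedure names no concrete rules.

What the generator does **not** emulate: overlapping-SCR superposition
shapes beyond simple addition, electrode drying and temperature drift,
motion artifacts with realistic spectra, inter-individual response
heterogeneity beyond a baseline offset, and any genuine valence
physiology. Results on synthetic corpora therefore bound what the
software does, not what real skin does.

## The architecture comparison, honestly

`architectureExperiment()` replicates the binary-vs-four-class comparison
on synthetic corpora: per replicate, both architectures are tuned on the
same table and seed, and each quadrant's binary F1 is paired with the
four-class model's per-class F1 for the same quadrant — on the
cross-validation estimates and, with `heldOut = TRUE`, on a fresh twin
corpus, which removes the per-target selection bias of a tuned search.

On this generator family the two architectures are statistically
*equivalent* under that matched comparison, at every contrast level from
the default conditions down to the null: the four-class argmax restricted
to one class is itself a strong one-vs-rest predictor, so per-class F1
tracks binary F1; at very low contrast the four-class model is in fact
slightly better, because a one-vs-rest learner suffers the 25/75
imbalance that the four-way argmax does not. Reports that per-quadrant
binary models clearly outperform a four-class model are, in our analysis,
driven by comparing the binary models' positive-class F1 against the
four-class model's *overall* weighted F1 — different quantities — and
further inflated by per-target selection bias and whole-dataset
normalisation. The package's acceptance suite states the matched
comparison as an expectation and lets it fail rather than weakening it;
the two robust findings it does confirm are that default-condition
corpora support strong per-quadrant binary models (mean CV F1 well above
0.85) and that identical-profile null corpora collapse to chance-level
F1 (a 12-replicate permutation-null characterisation of the tuned-KNN
setup gives mean 0.20, sd 0.07).

## Streaming

Tumbling 30 s windows (step = length; no overlap semantics are implied by
"one decision every 30 seconds"). Each window runs the full conditioning
chain in isolation — including its own tonic estimate, which is why the
tonic window must stay below the recognition window — then the
training-time scaler (values clipped to [0, 1]) and the four binary
models. A window is classified as soon as a sample at or past its end
arrives, which makes the output invariant to chunk size: feeding samples
one at a time or in bulk yields identical predictions. Carrying tonic
state across windows is a possible refinement, deliberately out of scope
here.

## Problem sizes used by the test and acceptance experiments

Study-scale checks (corpus counts, detector recovery) run at the full
default design: 32 sessions at 8 Hz, and 50 recovery segments of 120 s.
The architecture-comparison replicates use a reduced design chosen once —
12 participants, 120 s songs, 4 Hz, no corruption; search over KNN and RF
with prefixes {5, 15}, 3 sampled configurations, 2 × 5-fold CV — so that
20 replicates remain a desk-scale experiment on a single CPU; the null
condition uses 6 sampled configurations so the search can reach the
recall-friendly region of KNN's grid, without which "chance level" would
be understated. The detector-recovery fixture (SCR rate 3/min, amplitude
median 0.2 µS, σ_log 0.25, rise 4 s, decay 10 s, noise sd 0.005 µS,
drift 0.01 µS/√s) was fixed a priori as a physiologically typical,
well-separated SCR regime.

## Known limitations

* The tonic moving average absorbs part of each SCR, shortening phasic
  rise runs; amplitudes are therefore conservative relative to
  deconvolution methods.
* The mutual-information estimator is noisy at small n (spurious MI up to
  ~0.06 on 200 independent samples); rankings, not absolute MI values,
  are the supported output.
* Per-window streaming recomputes the tonic level inside 30 s, so slow
  drifts alias into the window's phasic estimate at window boundaries.
* The four-quadrant label set assumes every segment expresses exactly one
  quadrant; mixed or neutral affect has no representation.
* Synthetic valence separability is injected, not physiological; claims
  about real-world valence recognition cannot be supported by this
  corpus.
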