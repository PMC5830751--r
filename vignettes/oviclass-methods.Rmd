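---
title: "Behaviour classification from wearable IMUs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behaviour classification from wearable IMUs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oviclass)
```

## The problem

Direct observation of livestock behaviour does not scale; body-mounted
inertial sensors do. The question this package operationalizes is whether
three core sheep states — lying, standing, walking — can be recovered from
tri-axial accelerometer and gyroscope series, and how the three design
levers of an embedded deployment (sampling frequency, analysis window
length, sensor position) trade classification quality against battery
life.

## Signal model and processing assumptions

All processing operates on the per-sample Euclidean magnitudes of the two
sensors plus their first differences, four streams in total. Magnitudes
discard orientation, which buys robustness to how the tag sits on the
animal at the price of directional information — an assumption worth
keeping in mind if behaviours differing mainly in posture direction were
ever added to the ethogram.

The rate-of-change streams are plain first differences (per sample, not
per second; `derivative_scale` switches this). Features are computed per
window, so the choice only rescales the derivative features monotonically
and cannot change tree-based classification; we prefer the convention
with no hidden factor of `fs`.

Labels attach to samples by half-open interval containment
`[start_s, end_s)` with 0-based sample indexing; a sample exactly at a
bout start belongs to that bout. Samples outside every annotated interval
stay unlabelled, and any window touching one is dropped: a gap is an
annotation boundary of unknown behaviour and should not leak into
training.

## Windowing

Windows hold exactly `window_seconds × fs` samples and advance by half a
window (50% overlap). A window whose samples disagree is *mixed* and
takes its modal label; an exact tie goes to the temporally first label in
the window — deterministic and order-respecting where any rule would be
arbitrary. Mixed windows are retained (they are assigned a class, not
discarded), and the mixed percentage is reported per configuration. Note
this percentage counts windows; the analogous published summary calls its
rows percentages "of samples" while tabulating windows, an ambiguity we
resolve in favour of windows and flag here.

The derivative segment of a window holds the `n − 1` differences interior
to the window — no padding is invented.

## The 44 features

Eleven characteristics per stream: mean, standard deviation (sample,
`sd`), min, max, interquartile range (type-7 linear-interpolation
percentiles, the dominant numerics default), population excess kurtosis
`m4/m2² − 3` (0 for a constant window by convention; the common
signal-feature choice), zero crossings (strict sign changes after mean
centring, with exact zeros inheriting the previous nonzero sign so a
tangent touch is not a crossing), spectral entropy, dominant frequency,
and the signal areas `SA = Σw/fs`, `ASA = Σ|w|/fs`.

Spectral estimates use the raw one-sided periodogram of the untapered
window and natural-log Shannon entropy — the plain textbook formulas, with
no smoothing choices hidden inside. Two DC conventions differ on purpose:

* **dominant frequency excludes the DC bin** (configurable). The
  accelerometer magnitude rides on a ~1 g gravity offset; with DC
  included the feature would be 0 Hz for every window and carry no
  information.
* **spectral entropy keeps all bins**, as the formula is written; the DC
  mass is informative there (a flat-lying window concentrates probability
  at DC, lowering entropy).

Feature vectors are named `<feature>__<stream>` and ordered
alphabetically, so serialized models remain valid across sessions.

## Classifier

The ensemble follows the embedded design under study: 8 trees, bootstrap
bagging, and at each node 128 random candidates — a feature drawn
uniformly from the 44, a threshold uniform on that feature's range within
the node — scored by Gini impurity decrease, minimum one sample per leaf,
unbounded depth. "Random splits per node" is stated in the source design
without a selection criterion; Gini is the standard choice for randomized
forests, and both the criterion inputs and candidate counts are exposed in
`forest_config()`. Ties (argmax of class probabilities, equal split
scores) break deterministically by the fixed class order
lying < standing < walking and by first-generated candidate.

Windows are pooled before the stratified 70/30 split, matching the pooled
design of the study; with 50% overlap adjacent windows share half their
samples, so a random split leaks some information between train and test.
This is a faithful reproduction, not an endorsement — on real data a
grouped (per-bout) split would give a more conservative estimate.

## Evaluation

Metrics come from the observed (rows) × predicted (columns) confusion
matrix via one-vs-rest collapse; overall accuracy is the trace over the
total — the multiclass generalization of (TP+TN)/total consistent with a
single accuracy per configuration. A metric with an empty denominator is
reported `NA` (undefined), never 0. Agreement between the ear- and
collar-trained classifiers is a weighted Cohen's κ with equal-step
(linear) weights `|i−j|/(k−1)` over the fixed class order — the "equal
weights" convention of the classical agreement literature — computed on
held-out windows matched by start time; an unweighted variant is provided
since the classes are nominal.

## Energy model

In classification mode the IMU samples continuously, so bytes sampled per
hour and processing energy are constant; what a window-size choice moves
is (a) how often the processor reads a window's worth of samples
(`floor(3600/w)` per hour) and (b) how often the 256-byte SRAM buffer of
8-byte classification records fills and flushes to flash
(`floor(256/8)·w` seconds per flush, writes per hour rounded half-up).
Bytes per sample (14) follow from the published per-window byte counts.
The two per-event energy constants are *calibrated*, not specified:
least-squares fits of the published per-hour energy rows against the
event counts (≈0.2777 µA h per acquisition, ≈0.2611 µA h per flash
write); they live in `device_profile()` and are clearly marked as fitted.
Battery life uses a 365.25-day year, which reproduces the published
3.08/1.81-year projections at 10 and 17 µA h hourly drain to 2 decimals.

## The synthetic generator: what it does and does not emulate

No field recordings are public, so the generator is a first-class module.
It emulates the *structure* the analysis relies on:

* alternating behaviour bouts with exponential durations (one-parameter,
  memoryless; the simplest defensible bout law — real bout distributions
  are heavier-tailed). Mean bouts default to lying 240 s, standing 120 s,
  walking 60 s — resting states persist longer than locomotion, and these
  values put the mixed-window share at 3 s/16 Hz near 2%, the order
  observed in the field study;
* per behaviour: a fixed gravity orientation per bout (no orientation
  drift — adequate because downstream processing is magnitude-only),
  Gaussian per-axis noise (lying 0.02 g < standing 0.08 g < walking
  0.10 g), a 1.5 Hz, 0.35 g gait sinusoid for walking, gyroscope noise
  5/20/60 deg/s, and half-sine head-movement transients within standing;
* sensor position as a pure gyroscope amplitude gain (ear 2.0 > collar
  1.0), reflecting the much freer movement of an ear tag.

It does **not** emulate grazing or other unmodelled behaviours, sensor
detachment, orientation drift within bouts, integer sensor quantization,
or inter-animal variability. Synthetic separability is by construction
stronger than field separability: passing tests demonstrate that the
pipeline is correct and that its statistical machinery behaves as
designed, not that field accuracy would reach the same level. Accordingly
the package's accuracy figures on synthetic data (≈99%) sit above the
89–95% band reported on real sheep, and should.

All randomness flows from one root seed through named sub-streams (bouts
vs noise vs split vs bagging), so the annotation, the signals and the
whole grid are independently and jointly reproducible.

## Numerical and scale choices

* Spectral features are validated against an independent O(n²) DFT oracle
  to 1e−10 relative error on 1000 random windows up to length 256.
* Exponential bouts make single-track time shares noisy (sd = mean per
  bout): share-convergence properties are therefore tested on 160–280 h
  of simulated *annotation* (cheap — no signal synthesis), where the
  tolerances correspond to >3σ; signal-bearing tests use 10–120 min
  tracks, and the end-to-end acceptance run uses 2 h at 16 Hz — the scale
  of one field recording session.
* `floor(n/2)` stepping covers odd window sample counts, though every
  study configuration (24–224 samples) is even.
* Degenerate inputs are defined, not special-cased downstream: constant
  windows have kurtosis 0, entropy 0, dominant frequency 0 Hz; κ of two
  identical constant sequences is 1 (flagged degenerate).

## Known limitations

Single-animal, single-day abstraction (replicates pool before splitting);
no grouped split by default (fidelity over leakage hygiene, see above);
no feature-importance or model-comparison machinery; the energy model is
duty-cycle arithmetic, not register-level power simulation, and excludes
radio transmission.
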