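# oviclass

Classification of sheep behaviour — lying, standing, walking — from
body-mounted inertial measurement units (tri-axial accelerometer +
gyroscope), for researchers in biologging and precision livestock
monitoring who need a tested, reproducible desk-scale pipeline: from raw
sensor series to per-behaviour performance tables and an embedded
energy budget, swept over sampling frequency (8/16/32 Hz), window size
(3/5/7 s) and sensor position (ear vs collar).

## The method

Raw axes are collapsed to orientation-free magnitudes,

    Ā = √(Ax² + Ay² + Az²),   Ḡ = √(Gx² + Gy² + Gz²),

and their first differences form two further streams. The labelled
streams are cut into fixed windows with 50% overlap; a window spanning a
bout boundary is flagged *mixed* and takes its predominant label. On each
of the 4 streams, 11 feature characteristics are computed — mean, standard
deviation, min, max, interquartile range, kurtosis, zero crossings,
spectral entropy `SE = −Σ p(f)·log p(f)` of the normalized periodogram,
dominant frequency, signal area `SA = Σ Mag / fs` and absolute signal
area — giving a 44-dimensional feature vector per window.

The classifier is a bagged ensemble of randomized decision trees (8
trees; at each node 128 random (feature, threshold) candidates are scored
by Gini impurity decrease; minimum one sample per leaf), trained on a
stratified 70% split and evaluated on the held-out 30%: per-class
precision, recall, F-score and specificity from the observed × predicted
confusion matrix, overall accuracy, and a linearly weighted Cohen's κ for
agreement between ear- and collar-based classifiers.

Because no field data are deposited, the package ships a synthetic
generator that emulates the study structure (exponential behaviour bouts;
lying = low-variance gravity projection, walking = 1.5 Hz gait
oscillation, standing intermediate with head-movement transients; ear
gyroscope amplitudes scaled above collar), so the entire pipeline is
testable offline.

The embedded energy model converts a (fs, window) choice into duty-cycle
counts — sample acquisitions per hour, SRAM flush cadence, flash writes
per hour — energy components in µA h, and a battery-life projection for a
270 mA h cell.

## Worked example

```r
library(oviclass)

cfg     <- synthetic_config(duration_s = 3600, fs = 16, seed = 11)
ann     <- generate_bout_sequence(cfg)          # behaviour bout track
samples <- align(synthesize_recording(ann, cfg), ann)
res     <- run_pipeline(samples, window_seconds = 7, seed = 11, position = "ear")

res$cm
#>           predicted
#> observed   lying standing walking
#>   lying      232        1       0
#>   standing     1       42       0
#>   walking      0        0      32
res$metrics$overall_accuracy
#> [1] 0.9935275
res$metrics$per_class
#>      class precision recall f_score specificity
#> 1    lying     0.996  0.996   0.996       0.987
#> 2 standing     0.977  0.977   0.977       0.996
#> 3  walking     1.000  1.000   1.000       1.000
```

One hour at 16 Hz gives 1027 seven-second windows (4.3% mixed); the
held-out 30% (308 windows) is classified at 99.4% accuracy, with lying —
the most distinctive state — essentially perfect. The energy side:

```r
energy_table(16, c(3, 5, 7))[c(1, 3, 9, 10), ]
#>                  measure   3s  5s  7s
#> 1     samples_per_window   48  80 112
#> 3  acquisitions_per_hour 1200 720 514
#> 9      seconds_per_flush   96 160 224
#> 10       writes_per_hour   38  23  16
round(battery_life_years(10), 2)   # 16 Hz-class drain
#> [1] 3.08
round(battery_life_years(17), 2)   # 32 Hz-class drain
#> [1] 1.81
```

`run_grid()` sweeps the full 3 × 3 × 2 study grid from one root seed and
`report()` renders the mixed-window, accuracy, per-class, κ and energy
tables as CSV with a JSON manifest.

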