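---
title: "Cost-constrained wrapper feature selection for subject-independent emotion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-constrained wrapper feature selection for subject-independent emotion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectselect)
```

## The problem

Wearable chest sensors deliver two biosignals that carry autonomic
correlates of emotional state: the electrocardiogram (ECG, sampled at
250 Hz) and thoracic electrical bioimpedance (TEB, 100 Hz), whose
low-frequency component tracks breathing and whose higher band reflects
cardiac activity. `affectselect` implements a complete chain that turns
such recordings into a three-class decision (neutral, sadness, disgust)
and — the package's real subject — selects *which* features to compute,
under a hard bound on the operations per second (Nop) the deployed
pipeline may spend, while protecting the selection step itself from
overfitting to the small number of subjects typically available.

## Feature extraction

Each measurement channel is reduced to three slowly varying
physiological streams, resampled at 50 Hz:

* **PPM** — cardiac rate (pulsations/min),
* **RT** — respiration rate (breaths/min),
* **RD** — respiration depth (per-cycle amplitude).

The ECG's cardiac stream comes from a 30 Hz anti-aliasing low-pass
(`MFECG`); its respiration streams come from ECG-derived respiration via
a 3 Hz low-pass (`LFECG`) followed by a 0.1–0.5 Hz band-pass. The TEB
front end uses a 3 Hz low-pass (`LFTEB`) feeding both a respiration-band
(0.1–0.5 Hz, `RFTEB`) and a cardiac-band (0.8–2.9 Hz, `EFTEB`) filter.
The narrow band-passes are realized as interpolated FIR (IFIR) filters:
a short prototype whose taps are spread SF samples apart (SF = 25 for
ECG, 10 for TEB). Only every SF-th tap is nonzero, so the per-sample
cost falls by SF — the reason the cost model below charges an IFIR
filter N·F/SF against a plain FIR's N·F. The stretched prototype has
spectral images at multiples of fs/SF; the preceding anti-aliasing
low-pass removes them. All filters are linear-phase Hamming-windowed
designs at the orders in `filter_table()`, applied with group-delay
compensation and edge padding so outputs stay aligned and same-length;
low-passes are normalized to unit DC gain and band-passes to unit gain
at the band centre (measured pass/stop behaviour is asserted in the test
suite, not assumed).

Breath and pulse events are detected by an alternating min/max tracker
that treats the band-limited signal as approximately sine-shaped: an
extremum is committed once the signal retraces more than 20% of the
running peak-to-trough excursion, and detections closer than 0.4 of the
band's shortest admissible cycle are merged. These two thresholds are
the only tunables of the detector; they are deliberately coarse because
the inputs are already narrow-band. A signal with no detectable cycles
yields an *empty stream* — downstream, its features become `NA` and are
flagged, never an abort.

Event streams are converted to uniform 50 Hz series by
piecewise-constant interpolation (hold the last known value). Over each
60-second window (3000 samples), advanced every 10 s, 14 statistics are
computed per stream: trimmed mean 25%, median, 25th/75th percentiles,
kurtosis, skewness, standard deviation, mean absolute deviation,
geometric and harmonic mean, baseline, maximum, minimum, mean. With
2 measurements × 3 streams × 14 statistics this yields **84 features**
per emission, 42 per measurement.

Conventions that needed fixing:

* percentiles interpolate linearly between order statistics (R type 7);
* kurtosis is Pearson (non-excess; Gaussian reference 3), skewness the
  standardized third central moment;
* *baseline* is defined here as the mean of the samples at or below the
  window's 10th percentile — a floor-level summary distinct from the
  mean;
* geometric and harmonic means are undefined (reported `NA`) on windows
  containing non-positive values; the other 12 statistics are still
  computed;
* the 60-s window length is chosen so that the packaged per-statistic
  costs are consistent with an explicit operation count (the mean of a
  3000-sample window once per 10 s costs (2999 + 1)/10 = 300 ops/s,
  matching `statistic_ops("Mean")`).

Feature names use the `E_`/`TEB_` prefixes (`E_PPM_Mean`,
`TEB_RT_Max`, …); `feature_alias_map()` translates an alternative
dialect that spells the ECG prefixes `ECG_` and the TEB cardiac stream
`TEB_BPM`.

## The cost model

`build_cost_graph()` traces every feature to the blocks it needs:
filters, its stream's event estimator (PPM blocks 9050 ops/s, BPM
blocks 8800 ops/s — fixed constants of the real-time implementation,
not derived here), a 50 ops/s interpolator (one operation per 50 Hz
output sample; our own accounting convention, stated rather than
inherited), and its statistic. `mask_cost()` sums over the **union** of
blocks required by the selected features, so a filter shared by forty
features is charged once: Nop models the CPU load of one running
pipeline, and a second consumer of a filter's output costs nothing
extra. This makes the cost monotone and subadditive in the mask, which
the test suite checks by brute-force union enumeration.

## The classifier

The least-squares diagonal quadratic classifier (LSDQC) expands each
pattern $x \in \mathbb{R}^L$ to the augmented vector $(1, x, x^2)$ and
scores class $m$ as
$y_m = w_{m0} + \sum_n w_{mn} x_n + \sum_n v_{mn} x_n^2$ — axis-aligned
quadric boundaries, no cross terms. Stacking augmented patterns as
columns of $Q$ and one-hot labels as $T$, the weights minimizing
$\tfrac{1}{N}\|VQ - T\|^2$ are the closed-form (Wiener–Hopf) solution
$V = T Q^\top (Q Q^\top)^{-1}$. The decision is the row-wise argmax,
with ties broken deterministically toward the lowest class index. When
$Q Q^\top$ is numerically singular a ridge of $10^{-8}$ times its mean
diagonal is added; features are used raw (no standardization), which is
adequate at the O(1) scales the generator produces and keeps the
closed form exactly the one stated.

Validation is leave-one-subject-out (LOSO): one fold per subject, the
classifier trained on the rest. Per-fold MSE is computed as the
test-fold outputs against the test-fold targets — the only reading
consistent with evaluating a model where it was not trained — and the
reported error is the mean of per-fold error rates.

## The two selection criteria

Selection is a genetic-algorithm wrapper over binary masks, run
*inside* each outer fold (the held-out subject must not influence which
features are chosen for its own fold; a noise-replacement audit in the
test suite verifies this end to end). Two fitness functions are
compared:

* **SDEO** (standard design-error optimization): the MSE of the
  classifier trained and evaluated on the design subjects of the fold.
  Cheap, conventional — and structurally incapable of noticing that a
  feature's apparent usefulness is subject idiosyncrasy, because adding
  degrees of freedom never hurts a fit evaluated on its own training
  set.
* **KFBEO** (k-fold-based error optimization): an inner LOSO loop over
  the $S-1$ design subjects. For each inner subject $n$, a model is
  trained excluding both the outer subject $s$ and $n$, and scored on
  $n$; the pooled squared error over the $S-1$ inner folds, normalized
  by the design pattern count, is the fitness. A feature that only
  memorizes subjects raises this immediately.

Both are evaluated from per-subject sufficient statistics
($Q_k Q_k^\top$ and $T_k Q_k^\top$ of the *full* augmented matrix, from
which any fold-and-mask submodel is a row/column subset and one small
solve), so a KFBEO evaluation costs $S-1$ solves of a
$(2L'+1)$-dimensional system rather than any pass over the data. The
test suite pins both paths to literal brute-force nested-loop
computation at $10^{-10}$.

## GA design choices

Population 100, 200 generations, uniform crossover at rate 0.9, per-bit
mutation $1/L$, tournament size 2, elitism 2 (defaults of
`ga_config()`; all configurable). The Nop budget is a hard constraint
handled by *repair* — infeasible offspring have random selected bits
cleared until they fit — rather than by penalty terms, so the fitness
scale stays interpretable and every candidate ever evaluated is
feasible. Initial masks are drawn with inclusion probability aimed at
half the budget; empty masks are redrawn. The run length is a fixed
generation count, so a seed fully determines the outcome; each outer
fold reseeds deterministically from the top-level seed, making a fold's
result a pure function of (seed, design data, costs).

Repeated runs are summarized by `selection_frequency()`: the percentage
of attempts (repetitions × folds) in which each feature was selected,
conventionally reported above a 20% threshold. This ranking — not any
single run's mask — is the deployment-facing "best feature set";
per-fold masks are also reported, since the best single-fold mask and
the frequency ranking answer different questions.

## The synthetic generator

Real recordings are not shipped. Two generators stand in:

* `synth_recording()` emulates the raw signals: ECG as a raised-cosine
  pulse train at the class-shifted heart rate plus respiration-band
  wander and noise; TEB as a respiration sinusoid (class-shifted rate
  and amplitude) plus a small cardiac component. This is deliberately
  not a morphological ECG — the pipeline consumes only rate/amplitude
  streams, so waveform realism would add nothing the chain can see.
  Ground-truth rates are attached for oracle tests, which require the
  chain to recover them within 2%.
* `synth_feature_dataset()` emulates the tabular statistical structure
  that makes subject-independent selection hard: 3 balanced classes,
  informative features with class means spaced `class_gap` apart, and
  additive per-subject, per-feature random offsets. The offsets are the
  nuisance: on uninformative features they have scale `subject_sd`
  (default 3, dominating the default `class_gap` of 1), making those
  features pure subject idiosyncrasy; on informative features the scale
  is `subject_sd_informative` (default 0.5), modest individual
  variability that leaves the true markers transferable. Both scales on
  one dial would make *every* feature non-transferable and the
  comparison degenerate; separating them is what reproduces the
  selection pathology the nested criterion targets while leaving
  something worth selecting. Defaults are 8 subjects × 60 patterns (20
  per class) × 20 features with 2 informative — desk scale, chosen for
  minutes-not-hours runtimes; none of these effect sizes is calibrated
  to any particular recording campaign.

What passing tests on this generator do **not** show: robustness to
artifacts and electrode motion, to unbalanced classes, to non-additive
subject effects, or to the feature correlations a real physiological
pipeline induces. They do show that, under additive subject nuisance,
design-error selection reliably pads its masks with idiosyncratic
features and pays for it on held-out subjects, while the nested
criterion does not.

## Problem sizes used by the shipped checks

The acceptance-style tests run the paired comparison at the generator
defaults (8 subjects, 20 features, budget 10 unit-cost features, GA
population 40 × 40 generations, 20 paired repetitions), the
GA-optimality check on an 8-feature problem against exhaustive search,
and the oracle equivalences on 200 random small instances. The whole
suite runs in a few minutes on one core.

## Known limitations

* The event detectors are tuned for clean, band-limited input; they are
  not artifact-robust QRS detectors.
* The cost model counts abstract simple operations; it is a proxy for
  CPU load, not an instruction-accurate or energy model.
* `kfold_error()` with few subjects has high variance; with 2 subjects
  KFBEO is undefined (its inner loop needs a nonempty design set) and
  the package refuses rather than silently degrading.
* Feature standardization is off by default to keep the closed form
  exact; datasets with wildly heterogeneous scales may need it
  (`scale()` the matrix before `labeled_dataset()`).
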