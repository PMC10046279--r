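---
title: "Methods: ECG signal-quality classification under class imbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG signal-quality classification under class imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecgsqc)
```

## The problem

Continuously recorded biosignals from patient monitors contain large
amounts of unusable data: electrode detachment, motion, electrical
interference, pacing spikes and transmission gaps all corrupt the ECG.
Before any downstream model is trained on such data, each 20-second,
250 Hz single-lead segment (a vector of 5000 mV values) must be graded.
`ecgsqc` implements a three-class quality grading:

* **acceptable** — nearly flawless recording;
* **unacceptable** — severe flaws: extreme baseline sways or noise that
  render the QRS complexes indistinguishable for any duration;
* **uncertain** — mild noise or subtle sways, but QRS locations
  discernible throughout.

The central difficulty is class imbalance: in continuous monitoring around
95% of segments are acceptable. A classifier trained naively learns to say
"acceptable"; a classifier evaluated naively looks deceptively good. The
package therefore implements two classification strategies over two model
families and an evaluation scheme that exposes exactly this failure mode.

## Pipeline overview

1. **Synthetic generation** (`generate_segment`, `generate_dataset`) —
   labelled segments with contamination known by construction.
2. **Cleaning** (`preprocess_batch`) — exclusion of blank segments,
   ±5 mV extreme-value zeroing, isolated-zero interpolation.
3. **Features** (`extract_features`) — 43 hand-engineered time- and
   frequency-domain quality features for the random-forest models.
4. **2D transforms** (`stft_image`, `fft_image`,
   `sliding_window_matrix`) — fixed 80 × 100 image representations for the
   convolutional models.
5. **Models** (`train_rf`, `train_cnn`) — a warm-start random forest and a
   small 2D CNN, both trained under balanced resampling.
6. **Classification logic** (`one_step_classify`, `two_step_classify`) —
   direct 3-class argmax versus the binary-sequential cascade.
7. **Evaluation** (`evaluate_predictions`) — 3×3 and merged 2×2 confusion
   matrices with per-class precision/recall.

## The synthetic generator

The hospital waveforms behind this class of quality classifiers are not
publicly available, so the package ships a generator whose **labels are
true by construction**. A clean segment is a quasi-periodic train of beats;
each beat is a sum of five Gaussian lobes (P, Q, R, S, T) with fixed
relative amplitudes and widths, placed at beat times with 2% inter-beat
jitter. This is deliberately *not* a physiological simulator: it produces
detectable R-peaks with realistic rhythm statistics, which is what the
quality features consume, and nothing more.

Contaminations mirror what patient monitors produce: sinusoidal baseline
wander (default 0.15–0.5 Hz), white broadband noise, 60 Hz powerline
interference (configurable to 50 Hz), abrupt spikes (pacing-like artefacts
may exceed 100 mV), and blank (zero) runs from transmission gaps.

**Labelling rule.** The clinical labels are expert judgments; no
quantitative thresholds exist in the source material. The generator
therefore fixes stand-in thresholds, chosen once so the three regimes are
visually consistent with the class definitions at a ~1 mV QRS amplitude
(`label_thresholds()`): a segment is acceptable iff noise σ ≤ 0.05 mV and
wander amplitude ≤ 0.2 mV with no spikes or blanks; unacceptable iff
noise σ ≥ 0.30 mV (QRS visually lost in noise) or wander ≥ 1.5 mV
(excursions beyond the QRS height) or any spike is present; uncertain
otherwise. Dataset sampling ranges leave a margin to these thresholds so a
requested class is always realised.

Two consequences matter for interpreting test results. First, synthetic
classes are *more separable* than expert-labelled hospital data — passing
the recovery properties here shows the pipeline is correct, not that it
would reach any particular accuracy on real recordings. Second, the
unacceptable class's spike mode defaults to 2–4.5 mV amplitudes, below the
±5 mV clip, so that the contamination survives preprocessing; >100 mV
pacing-like spikes are available explicitly and are (by design) erased by
the cleaning chain.

## Cleaning chain

The order is fixed: exclusion, clipping, interpolation.

* A segment is excluded when fully blank or when any maximal blank run
  exceeds 0.5 s (strictly: 126 blank samples at 250 Hz are excluded, 125
  are kept). "Blank" covers exact zeros and missing samples, the two forms
  monitor gaps take.
* Samples with |value| > 5 mV are set to 0 (not truncated), matching how
  abrupt extreme values are handled upstream of annotation.
* Isolated zeros — both neighbours nonzero, assessed simultaneously on the
  input — are replaced by the neighbour midpoint. Boundary zeros and runs
  of ≥ 2 zeros are left; long gaps are the exclusion rule's job. The
  module interpolates *all* isolated zeros, a superset of the zeros
  created by clipping.

After the chain, a kept segment has its original length and no sample
above 5 mV in magnitude.

## The 43 features

Features 1–34 are time-domain, 35–43 frequency-domain (`feature_names()`
gives the canonical order). Definitions the source material leaves open
are fixed as follows:

* **Aggregation**: statistics are computed on five nonoverlapping 4-s
  subsegments and aggregated by mean and standard deviation, except
  `slopes`, which is the first difference of the full segment.
* **Peaks**: adaptive-threshold detection on the 0.5–8 Hz bandpassed
  signal (rolling-mean baseline over 0.75 s raised by a ladder of
  percentages; the candidate whose inter-beat intervals give a plausible
  rate, 40–200 bpm, with minimal RR variability wins). Amplitudes are read
  from the unfiltered signal. Fewer than two peaks triggers the sentinel
  policy.
* **Autocorrelation**: normalised ACF at lags 1..fs (1 s — one beat at
  ≥ 60 bpm), pooled over subsegments.
* **Cross-correlation / DTW**: computed between the four adjacent
  subsegment pairs; cross-correlation at lags ±1 s with ACF normalisation,
  DTW with absolute-difference cost and no alignment band, unnormalised.
* **Hurst exponent**: classical rescaled-range estimate per subsegment
  (geometric ladder of block sizes from 8 to half the subsegment, slope of
  log R/S vs log size).
* **Spectra**: `maxpower`/`maxfreq` from the one-sided FFT power spectrum
  per subsegment, excluding the DC bin (offset is not morphology);
  `meanpowerdiff`/`meanfreqdiff` are successive between-subsegment
  differences of that peak, aggregated by standard deviation. The STFT
  uses a periodic Hann window of 100 samples with 50% overlap; spectral
  entropy is the Shannon entropy (nats) of each frame's power-normalised
  spectrum.
* **Negated-signal (`_neg`) features**: peak detectors return peaks, not
  troughs, and ECG polarity flips abruptly in practice, so several
  features are recomputed on the sign-flipped waveform. On fixed
  subsegments many of these coincide analytically with their plain
  counterparts (autocorrelation, cross-correlation, kurtosis, Hurst, DTW
  and FFT power are polarity-invariant; skewness only changes sign); the
  implementation uses these identities, and only the peak-derived features
  genuinely differ. The registry nevertheless keeps all 43 names so the
  feature table's contract is stable.
* **Sentinels**: features undefined on degenerate input (constant signal,
  zero variance, < 2 peaks) are reported as 0 with a per-feature validity
  flag, keeping the vector fixed-width for the classifiers.

`select_k_best` ranks features by the one-way ANOVA F statistic between
classes (constant columns rank last); with k = 43 on this registry it is
the identity but preserves the pipeline's selection step.

## 2D input representations

All transforms emit exactly 80 × 100 matrices. The sliding-window form
cuts the segment into 999 windows of 10 samples at step 5, concatenates
them (9990 values), uniformly decimates to 8000 and reshapes row-major.
The window arithmetic (999 × 10 = 9990) does not equal 80 × 100 = 8000, so
*some* reduction is unavoidable; uniform decimation was chosen as the
least structured option and is isolated in one function so it can be
swapped. The STFT (Hann 100, 50% overlap) and windowed-FFT (rectangular
window, otherwise identical) images map the one-sided 51-bin × 99-frame
magnitude surface onto the 80 × 100 grid by linear resampling of both
axes; rows are frequency (0–125 Hz, `image_freq_axis()`), columns time.

## Models and training scheme

**Warm-start random forest.** Training runs 20 balanced-resampling steps.
Each step draws a fresh equal-sized sample from every class — re-drawing
from the abundant acceptable pool, so successive steps see new acceptable
segments — holds out 20% for validation, fits 50 new trees (bootstrap,
out-of-bag scoring) and appends them to the ensemble. The final model is
the full 1000-tree forest; per-step validation precision/recall and the
best-scoring step are recorded in `history`. Tree depth and
features-per-split stay at the `randomForest` defaults.

**Small 2D CNN.** Three convolution blocks with geometrically decreasing
feature maps (100, 50, 25) and correspondingly decreasing square kernels
(7, 5, 3 — sizes fixed here; only the decreasing pattern is prescribed),
each followed by average pooling with pool sizes 10, 5, 3 at stride 3;
then dense layers 128–64–32–16 and a softmax head. Activations are leaky
rectifications with negative-side slope 0.002 (a plain rectifier has no
such parameter, so the stated alpha is interpreted as the leaky slope).
Dropout keep probability is 0.5 on the hidden dense layers; L2 penalty
0.01 applies to all weights; the optimiser is Adam at learning rate 0.001
with batch size 50. Loss is cross-entropy (binary for the 2-class heads).
The network is implemented in-package with explicit im2col matrix algebra
and compiled kernels, which makes training exactly reproducible for a
fixed seed — a property the acceptance checks exploit.

The CNN uses the same balanced-resampling outer loop: each of up to 20
steps draws a fresh balanced sample, splits 80/20, and runs a small number
of optimiser epochs (`epochs_per_step`, default `max_epochs %/% n_steps`).
Early stopping monitors the cross-entropy term of the held-out validation
loss — the L2 penalty shrinks monotonically during training and would
otherwise mask convergence of the data fit — and by default stops at the
first step without improvement (patience 1, the usual early-stopping
convention; configurable). The returned model restores the checkpoint with
the highest validation precision + recall.

## One-step vs two-step classification

The one-step classifier is a 3-class argmax with a fixed tie-break order
(acceptable > unacceptable > uncertain). The two-step cascade trains its
first binary classifier only on acceptable + unacceptable segments — the
two sharply different classes; including the gray-zone uncertain class
disturbs this boundary — and its second only on unacceptable + uncertain.
At inference, step 1 decides acceptable vs other at probability 0.5 (the
threshold is a package choice; ties resolve along the global tie-break
order) and step 2 is consulted only for "other" segments. The rationale is
that under heavy imbalance the 3-class head sacrifices acceptable-class
recall, while the cascade protects it.

## Evaluation

Confusion matrices are truth-in-rows, prediction-in-columns, classes in
canonical order. Because the practical goal is selecting *usable* data,
the 3×3 matrix is additionally merged into a 2×2 matrix of
acceptable + uncertain vs unacceptable (block sums; totals conserved).
Precision, recall and accuracy come from both matrices; an empty
denominator yields an explicit `NA` marker, never a silent zero, so
degenerate test sets cannot inflate averages. Statistical significance
testing between approaches is out of scope.

## Problem sizes and numerical choices

The test-suite and acceptance studies run at a deliberately desk-sized
scale chosen once: the imbalance study uses 95/2.5/2.5% classes at
n = 2000 train / 1000 test with five training seeds; the recovery property
expects per-class recall ≥ 0.9 on these well-separated synthetic classes;
the CNN smoke study uses 200 images per class whose class means differ by
5σ in a pixel block, expecting ≥ 0.95 validation accuracy with the stop
condition reached within 20 steps. Performance on expert-labelled hospital
recordings cannot be reproduced without such data and is not a target of
any test here; the tests certify the pipeline's correctness and the
directional imbalance behaviour, nothing more.

Other fixed numerical choices: Butterworth order 3 with `filtfilt` for the
zero-phase bandpass; periodic (not symmetric) Hann windows; natural-log
entropy; Adam ε = 1e-8; probability threshold 0.5 in both cascade steps;
dataset proportional counts are floored with the shortfall assigned to the
last class.

## Known limitations

* The generator's beats are Gaussian-lobe caricatures: no arrhythmia
  morphology, no 12-lead geometry, no realistic pacing artefact shapes.
  Distribution shifts of real monitors (electrode pop, EMG bursts,
  clipping at the ADC rail) are only coarsely mimicked.
* The labelling thresholds are construction rules, not estimates of the
  expert decision boundary.
* Several `_neg` features are analytic duplicates under the fixed
  subsegment convention (see above); they are kept for registry fidelity
  but carry no extra information here.
* CNN training at the full 80 × 100 topology is CPU-minutes per study;
  the defaults trade epochs for steps accordingly.
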