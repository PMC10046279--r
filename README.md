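# ecgsqc — signal-quality classification for continuously acquired ECG

Continuously recorded ECG from patient monitors is full of unusable
stretches: electrode detachment, motion artefact, mains interference,
pacing spikes, transmission gaps. Any model trained or evaluated on such
data first needs every 20-second, 250 Hz segment (5000 mV samples) graded
for quality. `ecgsqc` implements that grading as a three-class problem —
**acceptable** (nearly flawless), **unacceptable** (QRS complexes
indistinguishable or severe sways/spikes), **uncertain** (mild flaws, QRS
locations still discernible) — for users building biosignal pipelines who
need an automatic, reproducible data-usability gate.

The scientific core is a comparison of two strategies under the heavy
class imbalance of real monitoring data (~95% acceptable):

* a **one-step 3-class classifier**: `ŷ = argmax_k p(k | x)`;
* a **two-step binary sequential cascade**: classifier 1 separates
  acceptable vs other (trained only on acceptable + unacceptable
  segments), and, only when a segment is "other", classifier 2 separates
  unacceptable vs uncertain (trained only on those two classes).

Each strategy is built for two model families: a warm-start random forest
over 43 hand-engineered time/frequency quality features (slope statistics,
peak-amplitude z-scores, autocorrelation/cross-correlation, skewness,
kurtosis, Hurst exponent, DTW distances between 4-s subsegments, FFT peak
power/frequency shifts, STFT magnitudes, spectral entropy), and a small 2D
CNN over fixed 80 × 100 time–frequency images. Training uses balanced
resampling: every step re-draws an equal number of segments per class,
growing the forest by 50 trees per step (1000 total) or advancing the CNN
a few epochs with early stopping on validation loss. Evaluation reports
the 3×3 confusion matrix and a merged 2×2 matrix (acceptable + uncertain
vs unacceptable) with per-class precision and recall, the merged view
reflecting the practical goal of selecting *usable* data.

Hospital waveforms of this kind are not redistributable, so the package
ships a synthetic generator producing labelled quasi-periodic QRS trains
with configurable contamination (baseline wander, broadband noise,
powerline interference, extreme spikes, blank runs); labels are true by
construction. See `vignette("ecg-quality-methods")` for the model details
and every convention the implementation fixes.

## Worked example

```r
library(ecgsqc)

cfg <- read_run_config()                 # study defaults, all seeds explicit
cfg$n_train <- c(80, 20, 20)             # acceptable / unacceptable / uncertain
cfg$n_test  <- c(40, 10, 10)
cfg$rf$n_repetitions <- 5L               # 5 x 50 = 250 trees
res <- run_pipeline(cfg)                 # generate -> clean -> features ->
print(res$report)                        # train cascade -> classify -> evaluate
```

```
<eval_report> 60 segments

3x3 confusion (rows = truth):
              pred
truth          acceptable unacceptable uncertain
  acceptable           40            0         0
  unacceptable          0           10         0
  uncertain             1            0         9
accuracy: 0.983

merged 2x2 (acceptable+uncertain vs unacceptable):
                      pred
truth                  acceptable+uncertain unacceptable
  acceptable+uncertain                   50            0
  unacceptable                            0           10
accuracy: 1.000

per-class precision (3x3): acceptable=0.976, unacceptable=1.000, uncertain=1.000
per-class recall (3x3):    acceptable=1.000, unacceptable=1.000, uncertain=0.900
```

One uncertain test segment is taken for acceptable (its mild wander sits
near the class boundary); after merging the usable classes the separation
from unacceptable is perfect. On synthetic data the classes are more
separable than expert-labelled hospital recordings, so treat these numbers
as a pipeline check, not a clinical benchmark.

The same stages are scriptable individually (`generate_dataset`,
`preprocess_batch`, `extract_features_batch`, `select_k_best`, `train_rf`
/ `train_cnn`, `one_step_classify` / `two_step_classify`,
`evaluate_predictions`), and a thin command-line front end with
`generate`, `preprocess`, `extract`, `transform`, `evaluate` and `run-all`
subcommands lives at `inst/cli/ecgsqc.R`.

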