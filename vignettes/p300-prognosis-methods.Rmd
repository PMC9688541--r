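---
title: "Methods: P300 detection accuracy as a prognosis indicator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: P300 detection accuracy as a prognosis indicator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Patients with disorders of consciousness (DOC) — unresponsive wakefulness
syndrome (UWS) and the minimally conscious states (MCS-/MCS+) — are
routinely assessed with the behavioural Coma Recovery Scale-Revised
(CRS-R), which is slow and prone to misdiagnosis because the patients can
barely move or speak. The P300, an endogenous positive event-related
potential (ERP) appearing roughly 300 ms after an attended oddball
stimulus, offers a motor-independent window on residual cognition. The
analysis implemented here asks a prognostic question: does the *accuracy*
with which a classifier can detect single-trial P300 responses in a
patient's EEG predict whether that patient's diagnosis will have improved
at a three-month follow-up, and does it track the CRS-R score?

The package provides four layers, mirroring the analysis it re-implements:

1. a **synthetic oddball EEG generator**, because the patient recordings
   themselves are not publicly available;
2. the **ERP preprocessing** chain (band-pass filtering, epoch extraction,
   decimated multi-channel feature vectors, grand-average waveforms);
3. two **single-trial P300 detectors** — a spatiotemporal CNN and a
   variational Bayesian multilayer perceptron — evaluated by stratified
   10-fold cross-validation, plus the confusion-matrix metric suite;
4. the **cohort statistics** linking per-patient detection accuracy to
   outcome, etiology and CRS-R, runnable directly on the packaged
   per-patient tables of the original 18-patient cohort.

The package follows the classic R modelling idiom: `p300_cnn()` and
`p300_bayes()` are fitting functions returning classed objects with
`predict`, `print`, `summary` and `coef` methods; `cross_validate()`,
`run_study_statistics()` and `run_pipeline()` return classed results with
`print`/`plot` methods. Internals are base R, with the two training loops
in compiled code.

# The synthetic generator

`generate_recording()` simulates a continuous 30-channel recording at
250 Hz with a stimulus schedule in which left/right flashes alternate at a
fixed stimulus-onset asynchrony and target/non-target order is randomised.
Design choices, each configurable:

* **P300 waveshape.** A positive Gaussian bump, 200 ms full width at half
  maximum, centred at 300 ms post-stimulus with per-event Gaussian latency
  jitter (default SD 20 ms). A smooth, delta-band-dominant deflection is
  the standard idealisation of the P3b; the true waveshape is not
  specified by the study, so only smoothness and timing are claimed.
* **Topography.** Weights peak at Pz/Cz (1.0) and decay frontally and
  occipitally — the classic centro-parietal P3b distribution. The weights
  multiply the bump amplitude per channel.
* **Background noise.** Independent per-channel 1/f ("pink") noise,
  exponent 1, 9 µV RMS, plus 2 µV white noise, plus a 1 µV common 50 Hz
  line component so the filtering stage has mains interference to remove.
  These values are a realistic single-trial regime for scalp EEG: the
  default 5 µV P300 is well below the noise floor on any single trial, and
  the resulting cross-validated detection accuracies fall in the 60–80 %
  band reported for DOC patients rather than at ceiling.
* **Timing.** Stimulus-onset asynchrony defaults to 800 ms — at least the
  600 ms analysis window plus margin, so consecutive epochs never overlap.
  The original inter-stimulus timing is not stated; no fidelity is claimed.
* **Class balance.** The generator takes explicit per-class counts rather
  than an oddball rarity parameter, because the published per-patient
  epoch counts are nearly balanced. `configs_from_epoch_counts()` maps the
  published count table onto an 18-patient cohort configuration.

What the generator deliberately does **not** model: eye blinks and EMG
beyond the generic noise floor, between-channel noise correlation,
non-stationarity, habituation, or any patient-specific ERP morphology.
Passing the synthetic tests therefore shows that the pipeline recovers a
known P300-like signal under realistic noise — not that it would reach any
particular accuracy on real patient EEG.

# Preprocessing

Two configurations of the same operations, mirroring the two descriptions
of the original procedure:

* **Detection path** (feeds the classifiers): band-pass 0.1–10 Hz,
  epochs 0–600 ms post-stimulus, no baseline correction, every 5th sample
  kept, segments of the ten channels Fz, Cz, P7, P3, Pz, P4, P8, O1, Oz,
  O2 concatenated → 10 × 30 = 300 features per flash.
* **ERP-figure path**: band-pass 0.1–20 Hz, epochs −50–600 ms,
  baseline-corrected on the −50–0 ms interval, averaged per class to
  grand-average waveforms.

Numerical choices:

* **Filter.** Zero-phase 4th-order Butterworth applied forward–backward
  (`signal::filtfilt`), standard ERP practice; zero phase preserves the
  P300 peak latency. The filter family was not specified.
* **Sample-window convention.** Half-open `[start, end)` with
  `index = floor(t * sfreq)`: 150 samples for 0–600 ms at 250 Hz, 163 for
  −50–600 ms, 13 baseline samples.
* **Decimation.** Plain take-every-5th sampling with no extra anti-alias
  stage: the detection path is already low-passed at 10 Hz, below the
  post-decimation Nyquist frequency of 25 Hz.
* **Channel count.** The original text builds 10-channel feature vectors
  in one place and says 30 channels were used in another; this cannot be
  resolved from the text. The default follows the explicit 10-channel
  recipe (300 features); `build_feature_vectors()` accepts any channel
  subset including all 30.
* **Artifact handling.** None beyond the band-pass, mirroring the original
  claim that filtering suffices; no ICA, no epoch rejection.

# The two detectors

## Spatiotemporal CNN

Feature rows are reshaped to a channels × time image. `Conv_1` is a
spatial convolution spanning all channels (kernel C × 1, 8 maps), `Conv_2`
a temporal convolution (1 × 5 across all maps, 8 maps); each is followed
by batch normalisation ("linear normalisation" paired with
training-speed claims is read as batch norm) and ReLU; `Conv_2` and a
32-unit hidden linear layer carry dropout; a 2-unit softmax closes the
network. The exact kernel shapes were not published; the
spatial-then-temporal factorisation is the standard reading of "2D
convolutions on the channels" for EEG. Training uses the published
configuration: Adam, batch size 16, weight decay 1e-4, dropout 0.3,
learning rate 4e-5, 100 epochs. No early stopping or validation split is
used (none was described). Accuracy is reported as pooled out-of-fold
accuracy; the mean of per-fold accuracies is also stored, since the
original aggregation rule is unstated.

## Variational Bayesian MLP

The Bayesian detector follows the weight-sampling scheme: on every
feedforward pass each weight and bias is drawn as

$$W = \varepsilon \cdot \mathrm{softplus}(\rho) + \mu,\qquad
  \varepsilon \sim \mathcal{N}(0, 1),$$

with trainable $(\mu, \rho)$ and $\mathrm{softplus}(\rho) =
\log(1 + e^{\rho})$ keeping the scale strictly positive — the printed form
of the sampling rule garbles this term, and softplus is the scale function
of the cited method. The architecture is a two-layer MLP (default hidden
width 64) on the same 300-dimensional features, with a standard-normal
prior; the objective adds KL(q‖N(0,1)) weighted by 1/num_batches to the
cross-entropy, which shrinks predictive variance. Prediction averages
softmax outputs over S = 10 weight draws. Whether the original Bayesian
model shared the CNN backbone is unstated; this implementation follows the
sampling equations with minimal extra assumptions. Training controls not
published for this model default to Adam at 1e-3, batch 16, 100 epochs.

Both trainers are written in compiled code with a self-contained seeded
RNG, so every fit, prediction and cross-validation is bit-reproducible
from its seed.

## Cross-validation

`cross_validate()` uses stratified, seed-shuffled k-fold partitions
(k = 10 by default; only "10-fold" was specified). Every training split
must contain both classes, folds are disjoint and cover all epochs, and
the per-patient detection accuracy is the pooled out-of-fold proportion
correct. A `constant_spec()` baseline classifier is provided; its pooled
accuracy equals the class proportion by construction, which the tests use
to pin the pooling arithmetic.

# Metrics

`compute_metrics()` implements the confusion-matrix suite with class 1
(P300) as positive: precision, sensitivity (= recall), specificity,
F1, F0.5, F2, NPV, accuracy and AUPRC. Two choices to note:

* **Specificity** is TN/(TN+FP). The printed formula divides by TN+TP,
  which would not be a fraction of negatives; it is treated as a
  typographical error.
* **AUPRC** is the step-wise sum over unique thresholds (equivalently,
  average precision), avoiding the optimism of linearly interpolated PR
  curves; it is invariant to monotone transforms of the scores.

Ratios with zero denominators are returned as `NA` and flagged, never
silently zeroed. Pooled and per-fold metrics are both reported: the
published per-patient metric tables are not mutually consistent under the
pooled reading (e.g. a printed precision/sensitivity pair implies an F1
that differs from the printed F1), so the original aggregation was likely
some unreported per-fold average; no attempt is made to reverse-engineer
it.

# Cohort statistics

`label_outcome()` encodes the outcome rule (improved = UWS→MCS-,
UWS→MCS+, or MCS-→MCS+; NTBI = acquired brain injury or cerebrovascular
disease). `run_study_statistics()` performs, per detector, the four group
comparisons (accuracy and F1 × outcome and etiology) as two-sided
pooled-variance Student's t-tests — "Student's t-test" is read literally;
Welch is available via `group_ttest(..., welch = TRUE)` — with
Benjamini–Hochberg adjustment across that family of four. The published
p-values match the *raw* pooled-t p-values, so the adjustment family used
originally is unknowable; raw and adjusted values are always reported
side by side and conclusions are stated against the α = 0.05 bound, which
holds under either. Gaussian fits (sample mean, n−1 SD) are descriptive,
for the group density plots, with no normality testing. The
accuracy–CRS-R correlation is Pearson's r against the follow-up
("after") totals, per the original figure captions; the before-score
variant sits behind a flag. Statistics on the packaged tables use the
accuracies exactly as printed (percent, 2 d.p.), since that is what the
original figures and tests evidently used.

One transcription note: in the packaged patient table, patient P11's
before-experiment CRS-R total is stored as 11, the sum of its printed
subscores, because the printed total (12) contradicts them and the
loader enforces total = subscore sum. No analysed statistic uses that
value.

# Test-scale configurations

The parameter-recovery check trains both detectors on synthetic patients
of 1000 epochs (500 per class) at amplitudes 0, 2, 4 and 8 µV across
three seeds, with 30 training epochs and, for the CNN, learning rate
1e-3. The published training configuration (100 epochs at 4e-5) targets
long training on patient-scale data; at desk scale it converges too
slowly to say anything useful about the *pipeline*, so the recovery tests
use a configuration that converges within the reduced step count. The
expected behaviour — chance accuracy at amplitude 0, monotone increase,
near-ceiling at 8 µV — is a property of the pipeline, not of a particular
hyperparameter setting. The grand-average ERP check uses 2000 epochs per
class so that background noise averages down well below the 10 %
amplitude tolerance.

# Known limitations

* The per-patient accuracies of the original cohort cannot be reproduced:
  the patient EEG is unavailable. The cohort statistics are reproduced
  from the published per-patient tables instead, and classifier behaviour
  is validated on synthetic data only.
* The generator's noise model is stationary and channel-independent;
  real EEG artifacts (blinks, EMG, electrode drift) are absent, so the
  synthetic accuracies say nothing about absolute performance on clinical
  recordings.
* The Bayesian detector is one defensible reading of a loosely specified
  model ("Bayesian network" text around weight-sampling equations); other
  architectures are compatible with the description.
* With n = 18 patients the cohort statistics have limited power, and the
  package makes no clinical-validity claim beyond reproducing them.
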