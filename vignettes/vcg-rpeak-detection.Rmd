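---
title: "R-peak detection on the 3D vectorcardiogram: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{R-peak detection on the 3D vectorcardiogram: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

R-peaks mark ventricular depolarization and are the reference points for
heart-rate measurement, beat classification and the synchronization of
imaging or interventional devices. In applications such as cardiac MRI a
*false* detection is far more damaging than a missed one, so the design goal
here is high positive predictive value without pre- or post-processing
heuristics.

`vcgrpeak` detects R-peaks in three stages:

1. **Vectorcardiogram reconstruction.** The eight independent leads of a
   12-lead ECG (I, II, V1–V6; the limb leads III, aVR, aVL, aVF are linear
   combinations of I and II) are mapped to three orthogonal axes by the Kors
   regression transformation, `V = E M`, where `E` is the `n × 8` lead matrix
   and `M` the published `8 × 3` coefficient matrix (`kors_matrix()`).
   Working on the 3-axis dipole removes the arbitrary choice of a "best"
   lead and makes the detector insensitive to per-lead R polarity.
2. **Semantic segmentation.** A compact 1D encoder–decoder network maps each
   normalized 4-s vectorcardiogram window (2048 samples at 500 Hz) to a
   per-sample R-peak probability. Targets are binary masks with a
   five-sample run centred on each annotated peak.
3. **Consensus peak extraction.** At inference, windows advance by half a
   window so every sample is predicted once or twice; predictions are
   averaged per sample, samples strictly above probability 0.5 hill-climb to
   their local maximum, and a maximum supported by at least five such
   samples becomes one detected R-peak.

Detections are scored against reference annotations with an inclusive
±75 ms tolerance (half the maximum QRS duration) by greedy one-to-one
matching, yielding recall, precision and F1 in percent.

## The network

The encoder applies six same-padded convolutions with kernels 9, 9, 6, 6,
3, 3 and 16, 16, 32, 32, 64, 64 filters; each of the last five is followed
by batch normalization and factor-2 max pooling, shrinking 2048 samples to a
64-sample bottleneck. The decoder mirrors this path with five stride-2
transposed convolutions (kernels 3, 3, 6, 6, 9; filters 64, 32, 32, 16, 16),
each batch-normalized, and concatenates the matching encoder feature map
after every upsampling stage. Dropout (rate 0.25) acts on the first decoder
convolution only; every convolution uses a leaky ReLU with negative slope
0.25 except the final kernel-9, single-filter convolution with a sigmoid.
The default configuration has exactly **79,409** trainable parameters —
small enough that the count doubles as an architecture fingerprint, checked
in the test suite.

The published description leaves some decoder details open (where the skip
concatenations attach, whether decoder stages are batch-normalized, the
kernel of the final layer). We resolved them by enumerating mirror-symmetric
decoders and keeping the unique configuration with genuine skip connections
whose parameter count equals the fingerprint: skips concatenate *after*
each upsampling stage, drawing on the pooled encoder outputs (and the first
convolution's activation at full resolution); decoder stages carry batch
normalization; the final convolution mirrors the first layer's kernel 9.
Convolutions keep their biases even when batch normalization follows — the
biases are redundant (their gradient is annihilated by the mean
subtraction) but they are part of the parameter count.

The engine itself (im2col convolutions backed by BLAS, transposed
convolutions as zero-stuffed convolutions, batch normalization, Adam,
binary cross-entropy backpropagation) is implemented in this package, with
the hot loops in C++; gradients are verified against central finite
differences in the test suite.

## Training protocol

Defaults follow the study protocol: Adam (learning rate 0.001), binary
cross-entropy, batch size 64, at most 500 epochs, early stopping with
patience 10. Two choices deserve comment:

* **Monitored loss.** No validation split is prescribed, so early stopping
  monitors the epoch-mean *training* loss; "improvement" means a strict
  decrease by more than 10⁻⁶, and the best epoch's weights (and batch-norm
  running statistics) are restored.
* **Class imbalance.** About 5 of every ~400 samples are positive. Plain
  (unweighted) cross-entropy is used, as prescribed; the network learns the
  prior quickly and the peaked masks afterwards.
* **Windowing conventions.** Training windows are non-overlapping
  (stride = window length) with ragged tails dropped — this convention
  reproduces the published per-database window counts exactly (439 windows
  per 30-minute 500 Hz record, 2 per 10-s record). The half-window stride
  is an inference-time device against border misses, not a training-set
  augmentation.
* **Sampling rate.** All records are resampled (polyphase, band-limited) to
  500 Hz before windowing; the published window counts for the 257 Hz
  database are consistent only with windowing at 500 Hz. `signal::resample`
  performs the interpolation; annotation indices are scaled and rounded.

Leave-one-out and cross-database protocols are provided
(`run_leave_one_out()`, `run_cross_database()`); both expose pooled
(summed counts) and macro (mean of per-record percentages) aggregation,
since printed benchmark tables do not always say which convention they use.

## Peak extraction details

The hill-climb rule is deterministic: from sample *s* move to the strictly
greater neighbour (the greater of the two if both are greater, ties to the
left); a plateau maximum is represented by its leftmost sample. "Above the
50% threshold" is strict (`> 0.5`), and the supporting count includes the
terminal maximum itself. The implementation is checked against a
brute-force steepest-ascent oracle on a thousand random traces.

`detect_rpeaks()` pads the record by edge replication so that the
half-stride tiling covers the ragged tail (the window list itself keeps its
strict every-window-fits semantics), and trims the averaged trace back to
the record length; without this, beats in the last fraction of a window
length are systematically unreachable.

The ±75 ms tolerance is compared in continuous time, inclusively; at 500 Hz
the effective integer window is ±37 samples. Precision with zero detections
(or recall with zero annotations) is reported as `NA`, never coerced to 0
or 100, and such records are dropped from macro averages with a warning.

## The synthetic generator

Real annotated 12-lead databases cannot be bundled, so the package ships a
generator (`generate_ecg()`) whose ground truth is exact by construction:

* a 3-axis cardiac dipole renders each beat as Gaussian P, Q, R, S, T waves
  (closed-form, ECG-dynamics-style); the annotation is the sample of the
  dipole-magnitude maximum of each beat;
* RR intervals are Gaussian around `60/mean_hr` (default 70 beats/min, a
  typical resting rate) with jitter `rr_sd` (default 0.05 s, mid-range
  short-term HRV), truncated at ±3σ and floored at 0.3 s;
* ectopic beats (optional) are premature by a factor 0.6 with doubled QRS
  width, inverted S and no P wave — the extrasystole morphology that
  dominates missed detections on real data;
* pacemaker spikes (optional) are one-sample 2 mV pulses 150 ms before each
  QRS;
* noise is additive: baseline wander (< 0.5 Hz sinusoid), 50 Hz powerline,
  broadband Gaussian, and enveloped muscle-artifact bursts;
* the lead projection is the pseudo-inverse of the Kors matrix, so the Kors
  transform of the clean synthetic leads recovers the dipole exactly, and
  every draw is reproducible from one seed.

What the generator does **not** emulate: genuine pathological QRS
morphologies beyond the stylized extrasystole, inter-patient morphology
variability, electrode-motion transients, or annotation jitter from human
annotators. Tests passing on synthetic data therefore demonstrate that the
pipeline's mechanics are correct and that the network can learn peaked
segmentation maps — they do not certify clinical-grade accuracy on real
arrhythmia databases.

## Numerical choices

* Min–max normalization to [−1, 1] is applied per extracted window and per
  channel; a constant channel maps to zeros (with a warning) rather than
  dividing by zero.
* Batch normalization uses ε = 10⁻³; running statistics use decay 0.9 (the
  convention of the PyTorch family — with desk-scale step counts, a 0.99
  decay leaves a visible initialization bias in the inference-time
  statistics). Evaluation mode uses the running statistics, so inference is
  deterministic and batching-invariant.
* The final convolution's bias starts at the logit of the expected label
  density (−4, about 2% positive samples: five mask samples per beat
  period), the usual initialization for heavily imbalanced segmentation.
  Without it, early optimisation steps are spent learning the class prior —
  wasteful at short training budgets. All other biases start at zero and
  weights are Xavier-uniform, as prescribed.
* Adam uses β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁷.
* The 1D k-means used to collapse interval-style annotations is initialized
  at evenly spaced order statistics and run with Lloyd iterations (cap 100),
  making it deterministic; centroids round half away from zero.
* Annotation indices are 0-based throughout, matching WFDB sample numbers.

## Scaled problem sizes

The test suite exercises the full-size network end to end on 60 clean
synthetic 60-s records (40 training / 20 held-out, 30 epochs), a deliberate
desk-scale stand-in for the database-scale experiments: large enough that
the detector must genuinely learn (≈560 training windows, ≈1400 test
beats), small enough to run on one CPU. Unit tests of the trainer use
reduced window lengths (64–256 samples), which exercise identical code
paths at a fraction of the cost. The Pan–Tompkins baseline follows the
canonical 1985 recipe (5–15 Hz band-pass, derivative, squaring, 150 ms
integration, adaptive dual thresholds with 200 ms refractory period, 360 ms
T-wave discrimination and 1.66·RR search-back); published comparisons used
an unspecified open-source variant, so single-lead comparisons against it
are indicative, not replications.

## Known limitations

* The HRV benchmark against the public 75-record arrhythmia database needs
  that database on disk (see `tests/testthat/test-acceptance.R` for the
  expected location); it cannot be shipped.
* Training is CPU-bound R/C++; it is adequate for desk-scale experiments,
  not for full-database replication.
* No refractory or physiological-plausibility post-processing is applied by
  design — the consensus rule is the whole decision logic.
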