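---
title: "Continuous decoding of hand-motion polar angles from EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous decoding of hand-motion polar angles from EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, the synthetic paradigm, the numerical
choices and the known limitations of `eegpolar`. It is the package's
methods account; the README shows a worked example.

## The decoding problem

A participant traces a circle of ~20 cm diameter with both hands while the
target moves clockwise at constant speed, completing one rotation in 6 s.
Each trial is 1 s preparation, 6 s movement, 2 s rest; 20 sessions of 10
trials give 200 trials per subject. EEG is recorded from 32 channels
(10-10 montage) at 256 Hz; an overhead camera samples the hand position at
an unstable 400-600 Hz.

The decoding target is the polar angle of the hand about the circle
center,

$$\theta = \begin{cases}
\arctan(y/x) & x > 0,\ y > 0\\
\pi + \arctan(y/x) & x < 0,\ y \neq 0\\
2\pi + \arctan(y/x) & x > 0,\ y < 0
\end{cases}$$

with $\theta = 0$ for $x \ge 0, y = 0$, $\theta = \pi/2$ for $x = 0, y > 0$
and $\theta = 3\pi/2$ for $x = 0, y < 0$, constrained to $[0, 2\pi)$ so the
clockwise rotation $\theta(t) = (2\pi - \omega t) \bmod 2\pi$ is continuous
over the interior of a trial and wraps only at the start/end point. The
wrap is deliberately *not* handled in the loss: decoders regress $\theta$
with plain mean squared error, so windows near the start/end point carry an
irreducible error contribution. A circular loss would change the method
being studied and is out of scope.

## Synthetic paradigm

The real recordings behind this analysis are not publicly deposited, so the
package generates subjects with the statistical structure the analysis
assumes. `simulate_trajectory()` produces the camera record: the target
angle as above, a first-order hand-tracking lag (default time constant
0.1 s; no lag statistics are published, so this is a plausible default,
deliberately left uncalibrated), smooth motor noise (moving-average
filtered Gaussian, default SD 0.3 cm), per-sample intervals drawn uniformly
from the reciprocal camera rate range, and rare momentary tracking losses
(Poisson, default expectation 0.05 per trial) injected as ~50 cm outliers
so the repair step has something to repair.

`simulate_eeg()` writes into the EEG, per trial:

* spatially correlated pink background activity (white noise shaped to a
  $1/f$ amplitude profile with a 0.5 Hz shoulder, mixed through a
  distance-based channel matrix; default RMS 20 uV);
* the angle code: `angle_gain` $\times\ [\cos\theta(t), \sin\theta(t)]$
  projected through a 32x2 channel topography (Gaussian bumps over C3 and
  C4 plus a Cz contribution), active only during movement (raised-cosine
  ramps inside the movement window, exactly zero outside it);
* alpha (10 Hz) and beta (20 Hz) oscillations with slow random amplitude
  envelopes whose amplitude drops by `erd_depth` during movement (ERD);
* a slow central negativity ramping up over the second before movement
  onset and sustained through movement (MRCP);
* frontal blink deflections (Poisson-timed 0.35 s pulses; subjects were
  asked to suppress blinks, hence the low default rate) and a 50 Hz
  line-noise sinusoid.

All randomness flows from one master seed through `derive_seed()` (a
Lehmer step on the 31-bit ring), so a configuration reproduces a subject
bit for bit.

What the generator does **not** emulate: volume-conducted source dynamics,
non-stationary artifacts (EMG, electrode drift or pops), cross-frequency
structure, or any nonlinear relation between kinematics and EEG beyond the
injected cosine/sine code. Passing the recovery tests therefore shows that
the pipeline recovers an angle code *of the assumed linear form* under
realistic noise — not that real cortex encodes angles this way.

## Preprocessing chain

Fixed order: 50 Hz notch -> 0.1-30 Hz zero-phase FIR band-pass ->
bad-channel interpolation -> common average reference -> per-session ICA
ocular removal -> epoching with baseline correction and downsampling.

* **Filters.** Hamming windowed-sinc FIRs with order set by the
  transition-width rule $N \approx 3.3 / \Delta f$; the 0.1 Hz low edge
  implies ~8,500 taps at 256 Hz, applied forward and backward by FFT
  convolution with odd reflection padding (zero net group delay). Signals
  shorter than the kernel are refused rather than silently corrupted.
* **Bad channels.** The visual inspection step is replaced by a
  reproducible proxy: robust z-score of log channel variance (threshold 5)
  and best-neighbor correlation (threshold 0.2). Interpolation is a
  Perrin-style spherical spline (order 4, 50 Legendre terms, ridge 1e-5)
  on idealized 10-10 positions, with an inverse-distance fallback if the
  spline system is singular; more than 25% bad channels is an error.
* **ICA.** FastICA is fit per session on a 1 Hz high-passed copy (ICA
  quality) and the unmixing is applied to the unfiltered data
  (low-frequency preservation). Ocular scoring replaces a trained
  classifier with a deterministic product of frontal topography
  concentration and sub-4 Hz source power fraction; components scoring
  >= 0.85 are removed in descending order, at most 3. A structural
  limitation of the dual-filter scheme is documented here deliberately:
  the unmixing is unconstrained on the sub-1 Hz subspace, so removing a
  blink component can leak a small fraction of very-low-frequency signal;
  the test suite bounds this leakage rather than pretending it is zero.
* **Epoching.** The analysis epoch is -0.5 to +6.5 s around movement
  onset; the baseline (-1 to 0 s, taken from continuous data) mean is
  subtracted per channel; epochs are then polyphase-resampled 256 -> 100 Hz
  (ratio 25/64), giving 32 x 700 per trial.

Angle labels go through `resample_uniform()` (linear interpolation to
1 kHz), `repair_outliers()` (neighbor-distance threshold 3 cm, iterative
neighbor-mean replacement, linear bridging of long runs), a per-session
least-squares circle fit standing in for the unrecorded screen/camera
calibration, the polar conversion, and wrap-safe decimation to 100 Hz
(anti-alias filtering of $\cos\theta, \sin\theta$ followed by conversion
back through the polar branches — filtering the wrapped angle directly
would smear the discontinuity).

## Dataset construction

Channels are standardized with the population SD; the default scope pools
all epochs of a subject, replicating a standardize-before-split workflow.
Note this lets test samples influence the statistics; `scope = "train"`
is available for methodologically stricter runs. Windows are 1 s (100
samples) stepped by 0.05 s (5 samples): a 700-sample epoch yields exactly
121 windows, and the label is the window's 50th sample (zero-based index
49, configurable). With a 100-sample (even) window that center sample sits
half a sample step from the window's circular mean under uniform rotation;
motor noise widens the gap, which is the qualitative origin of the small
center-vs-mean discrepancy expected in this windowing scheme.

Splitting is at trial level: a seeded shuffle, systematic sampling (every
k-th shuffled trial, phase 0) of 20 test trials, and 10 equal disjoint
folds from the rest. All 121 windows of a trial share its assignment, and
a leakage guard asserts the test/train trial sets are disjoint on every
fold of every run.

## Decoders

Six regressors: ShallowConvNet, DeepConvNet and EEGNet-8,2 style
convolutional networks, each with an optional hybrid variant in which the
flatten/linear head is replaced by two stacked 64-unit LSTM layers (first
returns the sequence, second its final state — the standard choice for a
scalar head) followed by a single linear unit. First-layer filter counts
are 40/25/8; dropout 0.2 everywhere; batch normalization as in the
canonical descriptions; the softmax that those architectures use for
classification is replaced by a linear output unit.

Kernel and pooling lengths are the canonical ones rescaled to the 100 Hz,
100-sample input: shallow uses a 0.1 s temporal kernel, 0.3 s average
pooling with 0.06 s stride, squaring and log nonlinearities; deep uses
0.05 s kernels with max-pool 2 per block and filter counts 25/50/100/200;
EEGNet uses a 0.125 s same-padded temporal kernel, a depthwise spatial
convolution (multiplier 2), and a separable convolution block with
average pools of 4 and 8. The resulting LSTM sequence lengths are 11
(shallow), 2 (deep) and 3 (EEGNet); a spec that collapses the temporal
axis below 2 steps is refused with advice to adjust pooling.

The networks are implemented in the package's own single-precision
C++ engine (temporal/spatial/depthwise/separable convolutions, batch
norm, ELU/square/log, pooling, dropout, LSTM, Adam). Backpropagation is
hand-derived and verified against central finite differences in the test
suite (30 random parameters per family, relative error < 2%). Weight
initialization is seeded Glorot-uniform with LSTM forget-gate biases at 1;
all dropout masks and initializations derive from the decoder seed, so
training is bit-reproducible on one machine.

## Training, evaluation, chance level

Loss is MSE, optimizer Adam at learning rate 0.002 without decay.
Mini-batches are whole trials — 9 trials (1,089 windows) under the full
protocol — shuffled each epoch; training stops when validation loss (the
held-out fold) has not improved for 50 epochs (cap 1,000), and the
best-validation weights are restored (the restore-best reading of early
stopping). Each fold's model is evaluated on the same held-out test set;
MSE (rad^2), MAE (rad), Pearson CC and R^2 are computed over the pooled
test windows, aggregated as mean +/- SD across folds; constant
(degenerate) predictions report CC = 0 with a flag, since permuted-label
models can collapse to the mean.

The chance level repeats the identical procedure with training and
validation labels permuted at window level (one fresh permutation per
fold; the stricter null compared with trial-level permutation); test
labels stay intact. `compare_to_chance()` runs a one-way fixed-effects
ANOVA per metric with folds as observations, plus an exact paired
sign-flip permutation p-value (enumerated up to 12 folds) as a
distribution-free companion.

### Scaled problem sizes

The package's own test and demonstration runs use scaled-down study
conditions chosen once: parameter recovery uses a 40-trial subject
(4 sessions), 4 test trials, 3 folds of 12, single-trial batches,
at most 35 epochs with patience 10, and a high-SNR encoding
(`angle_gain = 50`, background 4 uV); chance calibration uses a 30-trial
subject, 10 test trials, 10 folds of 2, at most 6 epochs with patience 3.
These sizes keep a full recovery-plus-chance comparison within minutes on
a single CPU core while leaving the protocol (window geometry, whole-trial
batching, loss, optimizer, early stopping) intact.

## Neural signatures

`compute_mrcp()` band-passes epochs to 0.1-4 Hz — a 4th-order Butterworth
applied forward and backward, since a windowed-sinc FIR for a 0.1 Hz edge
would be longer than an epoch — and returns per-channel across-trial means
with pointwise 95% t-intervals (no multiplicity correction, matching the
usual shaded-CI display). `compute_ersp()` uses Morlet wavelets on a
linear 4-30 Hz grid with cycles = freq/2 clamped to [3, 10], reflection
padding against edge bias, and expresses trial-averaged power in dB
relative to mean baseline power per frequency; the baseline interval
defaults to the 0.5 s of preparation inside the stored epoch. ERD of
depth $d$ in amplitude bounds the observable power change at
$20\log_{10}(1-d)$ dB (-6 dB at $d = 0.5$); the detection threshold used
in the tests is -2 dB. `channel_voltage_summary()` provides the numeric
substrate of voltage topography sequences (per-channel across-trial means
at requested times); spatial map rendering is out of scope.

## Known limitations

* The plain-MSE treatment of the wrap inflates MSE for windows near the
  start/end point; CC is less affected. This replicates the method under
  study rather than fixing it.
* Dual-filter ICA cannot guarantee preservation of sub-1 Hz signal along
  removed artifact directions (bounded, not eliminated; see above).
* The spherical montage is idealized, not digitized; interpolation and
  topography tests are accurate only to that idealization.
* Pooled-subject standardization mildly leaks test statistics by design
  (replication fidelity); use `scope = "train"` when that matters.
* The synthetic angle code is linear in $[\cos\theta, \sin\theta]$;
  decoder comparisons on synthetic data should not be read as rankings on
  real EEG.
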