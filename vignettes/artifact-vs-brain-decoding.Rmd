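---
title: "Brain versus artifact decoding of naturalistic movements from EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain versus artifact decoding of naturalistic movements from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdecode)
```

## The question the package answers

A movement decoder trained on EEG can be accurate for the wrong reason.
Naturalistic movements generate ocular and muscular potentials at the scalp
that are far larger than the brain's own in-band activity, and — crucially —
they co-vary with the movement being performed. A classifier that is free to
use whatever is most informative will happily learn the artifacts. For a
brain-computer interface used as an actuator this may even help; for one
meant to detect a *physiological brain state* (as in closed-loop
neurorehabilitation) it silently invalidates the whole premise.

`eegdecode` implements the complete analysis needed to quantify this risk:

1. separate multichannel EEG into **brain-only**, **artifact-only** and
   **all-component** conditions via ICA and a component labeler;
2. extract features along two independent routes — binned **time-frequency
   maps** with per-band PCA, and per-channel **log bandpower**;
3. decode five movement tasks per condition with one-vs-all linear
   classifiers (ECOC/SVM) or multiclass LDA, with simultaneously recorded
   **EMG** as a benchmark;
4. **interpret** the decoders: reproject classifier weights through the PCA
   and the ICA mixing matrix into sensor-space topographies, compute
   forward-model ("ideal") task patterns, and inspect brain-only data with
   multiclass CSP for residual artifacts.

Because the clinical recordings this kind of study uses are not publicly
available, the package ships a first-class synthetic session generator with
full ground truth, so that every stage — and the headline brain-vs-artifact
comparison itself — is testable at desk scale.

## The processing model

### Conditioning and epoching

Continuous EEG/EMG (64 + 7 channels at 1 kHz in the emulated protocol) is
downsampled to 500 Hz, high-pass filtered at 0.5 Hz, notch filtered at
50 Hz, and (EEG only) re-referenced to the common average; trials are then
epoched by the event markers (execution = task onset to completion, so
epochs have *variable length*) and each epoch's per-channel mean is
subtracted. Filters are Butterworth second-order sections applied
forward-backward (fourth-order magnitude, zero phase): phase distortion
would shift epoch content, which matters more here than the exact
transition band. The notch is a quality-factor-30 biquad: 5 Hz away the
response is within 1 dB of unity.

We deliberately perform no bad-channel or bad-trial rejection — artifacts
are the object of study, not a nuisance to be discarded early.

### ICA, labeling, and the three conditions

ICA is fit on the concatenation of all execution epochs with a symmetric
fixed-point algorithm (logcosh contrast, tolerance 1e-6, at most 200
iterations), after whitening by eigendecomposition. Common-average-
referenced data has rank `channels - 1`; the decomposition is therefore
computed on the retained-rank subspace, and the number of components is
configurable rather than assumed equal to the channel count. Components are
ordered by the share of sensor-space variance they explain, ties broken by
index. When more components are requested than there are clearly
non-Gaussian sources the residual subspace never stops rotating; the fit
then stops at the iteration cap with a message, which is expected behavior
rather than failure.

Automated component classification in the original setting is done by a
trained neural network. That dependency is replaced by a deliberately
transparent *rule-based labeler* with the same output contract — a
probability vector over \{brain, muscle, eye, heart, line noise, channel
noise, other\} — built from interpretable features: topography smoothness,
frontal and cap-edge concentration, single-channel dominance, and the
low (<4 Hz) / mid (4–30 Hz) / high (>40 Hz) spectral fractions plus a 50 Hz
peak ratio. The high-frequency boundary sits *above* the highest analysis
band on purpose: band-limited brain oscillations have almost no power
there while broadband muscle activity does, which is what makes the two
separable by rule. The labeler is pluggable — any function with the same
contract, including probability tables read from file
(`read_label_table()`), can drive the condition split.

The top 10 brain-labeled and top 10 artifact-labeled (muscle + eye)
components, in variance order, define the brain-only and artifact-only
conditions; the all-components condition keeps everything. Reconstruction
is linear (`mixing[, sel] %*% activations[sel, ]`), so conditions add up
exactly and selecting everything reproduces the input.

### Features

**Time-frequency route.** Per trial and retained component, a short-time
FFT (500 ms Hann windows, 75 % overlap) is averaged within the five bands
(theta 3–7, alpha 7–13, low beta 13–16, beta 16–26, gamma 26–40 Hz) and
into 10 equal time bins spanning the epoch, normalizing away duration
differences. Ten components give 10 × 5 × 10 = 500 features; an
all-components condition gives `k` × 50. Per-band PCA keeps 14 components
per band (70 total); the per-band rotations and centerings are stored so
classifier weights can later be reprojected *exactly*. Inside every
train/test split the PCA is refit on training rows only — the alternative
(fit once on everything) is a leakage risk we chose not to take, and the
unreduced table is always available for fidelity experiments. A
trial-averaged variant of the table exists for visualization only, since
trial-wise classification needs one row per trial.

**Bandpower route.** Per trial and channel the signal is band-passed and
summarized as `10 * log10(mean(x^2))` — decibel log bandpower. This is the
package's one-line numerical primitive and is oracle-tested to 1e-12
against an independent sum-of-squares implementation, including the closed
forms (a unit sinusoid is −3.010 dB; scaling by 10 adds exactly 20 dB). An
all-zero epoch would be −Inf and returns a −200 dB floor with a message.
64 channels give 64 features.

### Classifiers

The time-frequency features feed a multiclass one-vs-all reduction with
linear SVMs (fixed unit cost, *no* hyperparameter search), evaluated on 100
fresh stratified 80–20 train/test splits — random resplitting, not
resampling with replacement, since each repetition should see an intact
held-out set. The bandpower features feed multiclass LDA (SVD-based
solver, no explicit covariance inversion) under 10×10-fold stratified
cross-validation, giving 100 accuracy values per condition and band.
Sessions with fewer than 10 trials in a condition are excluded up front.
Stratification of the 80–20 split is our choice where the original is
silent; without it, small per-class counts make empty-class training sets
common.

Per-participant condition means are compared with a two-sided paired
Wilcoxon signed-rank test (a paired t-test is available via argument), with
stars at 0.05/0.01/0.001 and no multiple-comparison correction by default
(Holm via argument). The Wilcoxon default reflects small-n paired accuracy
data with no normality guarantee.

### Interpretation

For a linear decoder, the weight vector is a *backward* filter and cannot
be read as a scalp pattern. The package follows the forward-model route:
weights → (inverse of the stored per-band PCA) → component × band × bin
weight image → (ICA mixing matrix) → sensor topography → (× task
covariance) → the "ideal" task pattern. On Gaussian data this provably
recovers the generative pattern up to scale, and the package tests it
against planted forward models (|r| > 0.95). Bandpower topographies are
simple per-task trial means per channel.

Multiclass CSP (one-vs-rest generalized eigenproblems on Ledoit–Wolf-shrunk
class covariances, pooling the 4 filters whose class-variance ratio
deviates most from 0.5, near-duplicate directions dropped) is applied to
the brain-only condition only: its job here is not decoding but *auditing*
— if a variance-maximizing spatial filter on supposedly clean data shows an
ocular or muscular signature under the same rule-based labeler, artifact
leaked through the cleaning. The Ledoit–Wolf estimator is implemented
in-package and oracle-tested against a direct transcription of the
closed-form shrinkage intensity.

## The synthetic session generator

`simulate_session()` emulates the study protocol: five tasks in randomized
order, per trial a 2 s fixation, 4 s preparation, a variable-length
execution drawn uniformly from 2–6 s (so variable-length handling is
always exercised), and 2 s rest. Sources mix linearly onto an idealized
cap layout through smooth Gaussian-bump topographies (dipolar for brain),
which keeps ICA recovery and topography-correlation tests well-posed
without claiming biophysical head modeling.

* **Brain sources** (8 by default): a 1/f background plus a band-limited
  oscillation (bands rotate through theta/alpha/beta/gamma) under bursty
  amplitude modulation — the burstiness both mimics waxing-waning rhythms
  and provides the non-Gaussianity ICA needs. During execution the
  oscillation amplitude is scaled by `1 + brain_effect * g[task]`.
* **Artifact sources**: a frontal eye-blink train (~160 ms pulses, rate and
  amplitude task-modulated), a frontal left-right saccade source
  (step-like, ~50 ms transitions — ocular potentials are predominantly
  sub-5 Hz), two cap-edge neck/temporal muscle sources (broadband > 20 Hz
  carrier with tonic floor and phasic bursts), and a 50 Hz line source.
  Artifact class gains are biased so head-movement tasks drive ocular and
  neck sources harder, and artifact scalp amplitudes deliberately dwarf
  the brain sources — consistent with the physical situation the analysis
  is about, where ocular/muscular potentials exceed in-band brain activity
  by an order of magnitude or more.
* **Sensor noise** at 20 dB below the mixed-signal RMS by default:
  amplifier noise in practice is small relative to physiological signal.
  `snr_db = Inf` disables it, making the mixture exactly linear for
  oracle tests.
* **EMG**: 7 channels of rectifiable broadband noise whose execution-phase
  envelope follows a task-and-muscle-specific piecewise ramp/plateau
  template (the planted "fingerprint"), recoverable by the package's own
  envelope pipeline.

Identical configurations (including the seed) are bit-identical. The
ground truth (mixing columns, source kinds, class gains, event table,
templates, optionally the source activations) supports every recovery
oracle in the test suite.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: volume-conducted lead fields, non-stationary
artifact statistics, electrode drift and popping, imperfect event markers,
inter-participant variability, or any lesion physiology. Conclusions from
the synthetic benchmark are about the *pipeline's* correctness and about
the qualitative mechanism, not about clinical effect sizes.

## Reference configuration and problem sizes

The package's headline check asks whether the known qualitative result —
decoding accuracy ordered EMG ≥ all ≥ artifact > brain when artifacts are
more class-dependent than brain activity — emerges from the full pipeline.
The reference configuration (`reference_config()`) fixes the study
conditions: `artifact_effect = 0.8`, `brain_effect = 0.3`, 30 trials per
task across 5 tasks, default sensor noise, evaluated over 20 session
seeds. It runs on a reduced desk-scale montage — 24 channels sampled and
analyzed at 125 Hz with 16 ICA components — chosen so a full 20-seed sweep
is a coffee-break computation on a single core; channel count and rate do
not enter the ordering claim. The EMG benchmark uses the one-vs-all
harness, the three EEG conditions the bandpower/LDA route.

```{r ordering, eval = FALSE}
res <- ordering_summary(seeds = 1:20)
res$summary
# EMG >= all >= artifact > brain, artifact > brain in >= 18/20 seeds
```

## Numerical choices and degenerate inputs

* Resampling decimates after a zero-phase anti-alias low-pass at 0.45 of
  the target rate; event indices are floored, which is deterministic and
  never places an event past its phase.
* Epochs are half-open 0-based `[start, end)` everywhere; a trial with a
  missing completion marker is skipped with a warning rather than guessed.
* The TFA time bins average the STFT frames falling in each bin; on epochs
  too short to populate every bin the gaps are interpolated from
  neighboring bins. Per-band sampling noise on a single short epoch is
  large (few spectral degrees of freedom); flatness-under-stationarity is
  therefore a property of averaged maps, and the tests treat it that way.
* PCA ranks are capped at the available rank with a message; zero-variance
  feature columns are dropped per LDA training fold (with a majority-class
  fallback if nothing remains), so degenerate conditions (e.g. an empty
  component selection) degrade to chance instead of erroring mid-sweep.
* Ties in component variance are broken by index; CSP drops near-collinear
  filters (|cos| > 0.99) when pooling one-vs-rest solutions, which also
  makes the two-class case coincide with classical CSP, satisfying the
  whitening constraint `W'(C1+C2)W = I`.

## Known limitations

The labeler is a rule set, not a trained classifier: it is honest about
what it keys on, but it will misread component types whose signatures fall
outside those rules (it never assigns `heart`, for instance, since the
generator has no cardiac source). ICA separation quality — not the
labeler — is the binding constraint at low channel counts. The acceptance
pipeline's accuracies are properties of the synthetic benchmark and move
with its effect sizes; they are not predictions of accuracies on any real
recording.
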