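# eegdecode

Is your EEG movement decoder reading the brain, or the artifacts?

`eegdecode` is an R package for quantifying how much of the accuracy of an
EEG-based movement decoder is driven by genuine brain activity versus
movement-correlated artifacts (eye blinks, eye movements, muscle activity).
It is aimed at BCI and neurorehabilitation researchers who need their
decoder to reflect a physiological brain state — where an artifact-driven
classifier is a silent failure mode — and at anyone who wants a fully
synthetic, ground-truth-annotated EEG+EMG benchmark for decoding pipelines.

## What it does

The pipeline mirrors a complete movement-decoding study:

1. **Condition** continuous 64-channel EEG (+ 7-channel bipolar EMG):
   downsample to 500 Hz, 0.5 Hz high-pass, 50 Hz notch, common average
   reference, epoch by event markers (variable-length execution epochs),
   per-channel baseline.
2. **Separate** the EEG into three conditions with ICA over the
   concatenated execution data: the top-10 *brain* components, the top-10
   *artifact* (muscle + eye) components, and *all* components. Component
   classes come from a transparent rule-based labeler with the standard
   7-class probability contract (external label tables can be injected).
3. **Extract features** two ways:
   - *time-frequency*: per-trial STFT power in theta/alpha/low-beta/beta/
     gamma x 10 time bins per component (10 x 5 x 10 = 500 features),
     reduced to 70 by per-band PCA (14 per band);
   - *bandpower*: per-channel decibel log power of the band-passed trial,
     `10*log10(mean(x^2))` (64 features).
4. **Classify** five movement tasks: one-vs-all linear SVMs (ECOC) over 100
   stratified 80-20 splits for the TFA route and EMG benchmark; multiclass
   LDA under 10x10-fold CV for the bandpower route; paired Wilcoxon
   comparisons across conditions; per-band sub-analyses.
5. **Interpret**: reproject classifier weights through the stored PCA and
   the ICA mixing matrix into sensor topographies; turn backward filters
   into forward-model task patterns via the task covariance; audit the
   brain-only condition with Ledoit-Wolf-shrunk multiclass CSP for
   residual artifact signatures.

A synthetic session generator (`simulate_session()`) emulates the
experimental protocol — five tasks, fixation/preparation/execution/rest
phases, brain sources with band-limited class-modulated oscillations,
blink/saccade/muscle/line-noise artifacts whose class dependence is
stronger than the brain's, task-specific EMG envelope templates — with
bit-identical output under a fixed seed and full ground truth for recovery
oracles.

## Worked example

```r
library(eegdecode)

# a desk-scale session: 24 channels at 125 Hz, 30 trials per task,
# artifacts more class-dependent (0.8) than brain activity (0.3)
cfg <- reference_config(seed = 3)
sim <- simulate_session(cfg$session)

report <- run_experiment(list(sim), cfg$pipeline, approaches = "bandpower")
glance(report)
```

```
#> # A tibble: 4 × 4
#>   approach      condition mean_accuracy n_participants
#>   <chr>         <chr>             <dbl>          <int>
#> 1 bandpower_lda all               0.761              1
#> 2 bandpower_lda artifact          0.751              1
#> 3 bandpower_lda brain             0.445              1
#> 4 emg_ecoc      emg               1                  1
```

Reading the numbers: chance for five balanced classes is 0.20. The EMG
benchmark decodes the movement essentially perfectly; using *all* EEG
components comes close behind; the *artifact-only* reconstruction decodes
far better than the *brain-only* one — on this synthetic session the
decoder's accuracy is mostly artifact-driven, which is exactly the
situation the package is built to expose. Averaged over the 20-seed
reference sweep (`ordering_summary(seeds = 1:20)`) the means are
EMG 1.00 ≥ all 0.74 ≥ artifact 0.63 > brain 0.51, with artifact > brain in
19 of 20 seeds.

Inspect what the decoder used:

```r
eeg <- eegdecode:::process_session_eeg(sim, cfg$pipeline)  # or step by step
tbl <- tfa_feature_table(eeg$conditions$brain)
fit <- ecoc_train_test(tbl, per_band_k = 14, seed = 1)
img <- reproject_weights(fit$model)        # component x band x bin weights
autoplot(img)

csp <- fit_csp_multiclass(eeg$conditions$brain$epochs)
csp_artifact_screen(csp, eeg$conditions$brain$epochs, sim$truth$layout)
```

The methods vignette (`vignettes/artifact-vs-brain-decoding.Rmd`) documents
the model, every default, the synthetic generator's scope, and the
numerical choices.

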