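# megmvpa

Time-resolved multivariate decoding of event-related MEG data.

Experiments on the temporal dynamics of visual processing — when does the
brain's response start to distinguish an angry from a neutral face? — are
typically analyzed by training a classifier on the spatial pattern of MEG
sensor (or source) values at every sampled timepoint and asking when
decoding first exceeds chance. `megmvpa` implements that pipeline end to
end, for methodologists and MEG researchers who need a tested, seeded,
fully scriptable reference implementation:

* **Stimulus tools** — Fourier amplitude-spectrum equalization across an
  image set, phase-scrambled noise stimuli, GIST spatial-envelope
  descriptors, and image-level control classification.
* **Preprocessing** — zero-phase Butterworth band-pass and mains comb
  filters, baseline correction, fiducial-coil motion rejection (5 mm rule),
  pseudo-trial averaging (groups of 5), evoked responses, global field
  power and data-driven component windows (M100/M170/M220).
* **Decoding** — a linear L1 soft-margin SVM (SMO solver in C++, box
  constraint c = 1) under stratified 5-fold cross-validation with
  training-fold standardization; deployed per timepoint on anatomical
  sensor sets, as a neighborhood searchlight over ~16 ms windows, and on
  source-space virtual channels; orthogonal (face-vs-scrambled) feature
  selection.
* **Source space** — spherical-conductor forward models on a 6 mm grid,
  LCMV beamformer with unit-gain, vector-norm-normalized weights and
  optimal source orientation, atlas-ROI spectral-peak virtual channels.
* **Relevance** — the weights-to-activation-pattern transformation
  `a = C w`, windowed/baselined/normalized group maps, sign-flip
  permutation inference with max-statistic and Bonferroni control.
* **Inference** — conservative permutation p-values `(b+1)/(m+1)`,
  label-shuffle nulls, maximum-statistic FWER control, FDR with temporal
  cluster filtering (clusters of at least 5 significant timepoints) and
  onset estimation, BCa bootstrap confidence intervals, ERF randomization
  tests.
* **Synthetic MEG** — a seeded generator producing multi-subject epochs
  with known effect topography, onset and amplitude, 1/f-plus-white
  spatially correlated noise, EOG transients and coil-motion traces, so
  every stage above is testable without any recordings.

The statistic at the heart of the timecourse analysis: per timepoint
`t`, cross-validated accuracy `A(t)`; a label-shuffle null gives
`p(t) = (b+1)/(m+1)`; Benjamini–Hochberg FDR at α = .05 plus a 5-sample
cluster rule yields the significance mask, and the decoding **onset** is
the first sample of the first surviving cluster.

## Worked example

Simulate one subject with a known angry-vs-neutral effect starting at
100 ms, preprocess, and decode the timecourse:

```r
library(megmvpa)

array <- make_sensor_array(32)
cfg <- simulation_config(
  n_subjects = 1, n_trials_per_condition = 120,
  conditions = c("angry", "neutral"), sfreq = 200,
  epoch_window = c(-0.2, 0.5),
  effect_spec = list(list(pair = c("angry", "neutral"), onset = 100,
                          duration = 300, amplitude = 2.5, seed = 201)),
  seed = 42)
subj   <- simulate_dataset(cfg, array)[[1]]
epochs <- baseline_correct(subj$epochs, c(-0.2, 0))
kept   <- reject_trials(epochs, 5)$epochs     # 5 mm coil-motion rule
pseudo <- subaverage(kept, 5, seed = 1)       # groups of 5 trials
pseudo
#> MEG epochs [S01]: 48 trials x 32 channels x 141 timepoints @ 200 Hz
#>   window -0.200..0.500 s; units a.u.
#>
#>   angry neutral
#>      24      24

res <- timeresolved_decode(pseudo, c("angry", "neutral"), seed = 2)
res <- decode_inference(res, n_perm = 199, seed = 3)
res
#> Time-resolved decoding: angry vs neutral
#>   48 observations, 32 channels, 141 timepoints
#>   peak accuracy 1.000 at 120 ms
#>   onset of significant decoding: 110.0 ms
```

The decoder reaches perfect accuracy shortly after the injected 100 ms
onset, and the FDR+cluster onset estimate (110 ms) recovers the ground
truth within one or two samples — the effect needs a few milliseconds to
ramp up and clear the permutation floor. `plot(res)` draws the accuracy
timecourse with the significance mask; `run_pipeline(pipeline_config(...))`
chains all stages (simulation, preprocessing, ERF tests, searchlight
feature selection, emotion decoding, optional source space and relevance
maps) from one seeded YAML-serializable configuration.

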