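---
title: "Methods: time-resolved MVPA decoding of MEG data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved MVPA decoding of MEG data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`megmvpa` implements a complete multivariate decoding pipeline for
event-related MEG experiments of the kind used to study the temporal
dynamics of visual (e.g. emotional face) processing: stimulus-set
equalization in the Fourier domain, epoch preprocessing, time-resolved and
searchlight linear-SVM decoding, LCMV beamformer source reconstruction with
atlas-ROI virtual channels, transformation of classifier weights into
activation ("relevance") patterns, and permutation-based statistics. A
synthetic-MEG generator with fully known ground truth is a first-class
component: every stage of the pipeline is validated against data whose
effect topography, onset and amplitude are chosen by the tester.

# The decoding model

At each sampled timepoint $t$ the feature vector of a trial is the vector of
sensor (or virtual-channel) values $x_i(t) \in \mathbb{R}^d$. For a binary
condition pair, a linear L1 soft-margin support vector machine

$$\min_{w,b,\xi} \tfrac{1}{2}\|w\|^2 + c \sum_i \xi_i
\quad\text{s.t.}\quad y_i (w^\top x_i + b) \ge 1 - \xi_i,\; \xi_i \ge 0$$

is trained with box constraint $c = 1$ and evaluated by stratified 5-fold
cross-validation; accuracy is pooled over folds (the proportion of correctly
classified cases), and F1 is computed from the pooled confusion matrix with
the alphabetically first condition as the positive class. Features are
z-scored per fold using the mean and standard deviation of the *training*
split only; the leaky alternative (`standardize = "pooled"`) exists solely
as a negative control. The solver is a sequential-minimal-optimization
(maximal-violating-pair) routine on the dual, written in C++ because the
pipeline fits the classifier hundreds of thousands of times per analysis; on
a fixed 6-point fixture its weight vector agrees with libsvm (`e1071`) to
better than $10^{-4}$.

Before decoding, trials are averaged within condition in random groups of 5
("pseudo-trials") to raise SNR; remainder trials are discarded rather than
pooled into a smaller group so pseudo-trial SNR stays homogeneous.

## Deployments

* **Sensor sets** — decoding per timepoint on four anatomically defined
  channel groups (occipital, temporal, parietal, frontocentral), assigned
  from angular sensor position.
* **Searchlight** — each channel plus its directly connected neighbors
  (distance-threshold graph; on a 64-275 channel cap the threshold is tuned
  so searchlight sizes fall in the 4-10 sensor band typical of whole-head
  gradiometer templates), decoded over consecutive 10-sample (~16 ms at
  600 Hz) windows.
* **Orthogonal feature selection** — the searchlight is run on the
  face-vs-scrambled contrast (all emotion labels collapsed to `"face"` by
  `relabel_faces()`, which makes the contrast provably invariant under
  emotion-label permutation); channels whose searchlight is significant in a
  required fraction of subjects (default 100%) become the feature set for
  emotion decoding.
* **Source space** — whole-brain decoding on one virtual channel per ROI
  (84 by default), obtained with an LCMV beamformer.

# Inference

All significance statements are permutation-based with the conservative
estimator $p = (b+1)/(m+1)$, which can never fall below $1/(m+1)$.

* **Timecourses** — per-timepoint p-values from an $m$-iteration
  label-shuffle null (labels permuted across training and test sets, folds
  reassigned per permutation), Benjamini–Hochberg FDR adjustment, then
  removal of significant runs shorter than 5 samples. The **onset** is the
  first sample of the first surviving cluster. The order is deliberately
  FDR-then-cluster-filter (a run-length filter on FDR-significant samples),
  not cluster-level permutation.
* **Peak statistics** — the peak accuracy is tested against the
  permutation distribution of the *maximum* accuracy across timepoints
  (`p_peak_corrected`), which accounts for the selection of the peak. The
  fixed-timepoint convention (null evaluated only at the observed peak,
  `p_peak_observed`) is also reported for comparison; it ignores selection
  and is anticonservative, so calibration claims in this package always use
  the max-corrected form.
* **Searchlight maps** — per-subject p at the subject's own peak
  post-stimulus window by default; a fixed window (for a group-peak
  convention) can be passed instead. Group maps are the proportion of
  subjects significant per centroid.
* **ERF window tests** — sensor-wise paired t (two conditions, two-sided)
  or one-way repeated-measures F across subjects on window-averaged evoked
  responses, with within-subject condition permutation and max-statistic
  correction across sensors. For two conditions $F = t^2$ exactly, which the
  tests assert. Degenerate cells (zero variance under no effect) yield a
  statistic of 0 rather than NaN.
* **Relevance maps** — group inference by sign-flip permutation (default
  5000 iterations) on baselined per-subject maps, max-statistic correction
  across ROIs within each window, and Bonferroni division of $\alpha$ by the
  number of windows. One-sided (relevance above baseline), because map
  values are magnitudes.
* **Bootstrap CIs** — BCa intervals of the mean (default 1000 resamples):
  bias correction from the bootstrap CDF at the observed mean, acceleration
  from jackknife skewness; with both forced to zero the interval reduces
  exactly to the percentile interval. Identical samples return a degenerate
  flagged interval.

# Source reconstruction

The forward model places sources on an isotropic grid (default 6 mm) inside
a spherical conductor and evaluates the magnetic lead field analytically
(Sarvas formula, radial-gradiometer projection, constant factors dropped —
units are arbitrary, which is irrelevant for decoding after
standardization). In a spherical conductor radial dipoles are exactly
silent; each source's lead field is therefore pre-reduced by SVD to its
non-silent subspace, and the beamformer orientation search runs inside that
subspace (otherwise the near-null radial direction would spuriously
maximize output power).

LCMV weights use the broadband (0.1–100 Hz) covariance of all trials with
diagonal loading at 5% of the mean eigenvalue — the covariance inversion is
otherwise fragile at realistic trial counts, so regularization is on by
default and logged. Orientation is the output-power-maximizing direction
(smallest-eigenvalue direction of $L^\top C^{-1} L$); an SNR-optimal variant
(generalized eigenproblem with $C^{-2}$) is available. Weights are
unit-gain ($w^\top l = 1$, exact by construction) and then normalized by
their vector norm, which equalizes the white-noise floor across depth (the
depth-bias mitigation the tests verify on a two-depth comparison). ROI
virtual channels are the per-ROI spectral-power peaks: band power is
integrated analytically as $w^\top C_{band} w$ from Hanning-tapered trial
spectra (default 1–100 Hz; the band is a documented choice, since "peak"
selection statistics vary between labs), with ties broken by lowest grid
index. The bundled atlas is a synthetic k-means parcellation of the grid
(84 regions by default) — a stand-in with AAL-like granularity so tests
and demos run without external files; any volumetric NIfTI+TSV atlas can
be substituted.

# Relevance patterns

Linear-SVM weights are a backward model; they are turned into interpretable
activation patterns by multiplication with the feature covariance,
$a = C w$. For whitened features ($C = I$) the pattern equals the weights
exactly, and on a generative model $x = a s + \text{correlated noise}$ the
pattern recovers the true mixing vector where the raw weights need not — a
property the acceptance checks quantify (correlation > 0.95 at SNR 5). For
the map, the model is refit per timepoint on *all* pseudo-trials (no CV —
no generalization claim is attached to patterns), using full-data
standardization and the covariance of the same feature matrix. Magnitudes
are averaged within 100 ms windows (default tiling of 0–500 ms), baselined
by the pre-stimulus window, and normalized per subject to max-abs 1 before
group averaging; sign is discarded by default because it depends on the
arbitrary class-label convention (signed maps are available). Whether
normalization should be per subject or at the group level is genuinely open;
per-subject is the default because it prevents single subjects with large
raw magnitudes from dominating the group mean.

# The synthetic generator

`simulate_dataset()` emulates a multi-subject emotional-face MEG experiment:
by default 14 subjects, four conditions (angry, happy, neutral, scrambled)
with 180 trials each, 600 Hz sampling over −0.5…1 s epochs, and three
evoked components with M100/M170/M220-like latencies (100/160/240 ms)
whose smooth random topographies are shared across conditions and subjects.
Condition differences are injected *only* as additive low-rank
spatiotemporal patterns — a unit-norm topography times a smoothed boxcar
(20 ms ramps) from the effect onset — so the ground truth of every contrast
is exact and pre-onset data are exchangeable across conditions by
construction. The default effects mirror the qualitative structure of the
paradigm: a strong face-vs-scrambled pattern from 80 ms and weaker pairwise
emotion effects with onsets of 90–113 ms (angry contrasts earliest).
Noise is spatially correlated 1/f ("brain") noise plus white (sensor)
noise; the 1/f component's spectral exponent is a contract the tests verify
(slope recovered within 0.2 over 1–80 Hz). EOG channels carry
condition-independent blink/saccade transients by default, with an option
to correlate blinks with a condition as a positive control for EOG-driven
decoding. Fiducial-coil displacement is a bounded 3-D random walk whose
default bound (3 mm) stays under the 5 mm rejection threshold; raising the
bound exercises the rejection path.

What the generator does *not* emulate — and hence what passing tests do not
show about real recordings: realistic anatomy (BEM head models, cortical
geometry), inter-subject variability of component topographies, correlated
artifact families (muscle, cardiac), non-stationary noise, or overlapping
responses from fast stimulus sequences. Results on synthetic data validate
the *machinery* (calibration, localization, onset recovery), not effect
sizes in any real dataset.

# Preprocessing choices

* Filters are IIR Butterworth, applied forward-backward (zero phase) so
  onset latencies are interpretable; the band-pass is realized as cascaded
  high- and low-pass halves, which is numerically better conditioned than
  the direct band-pass polynomial when the band spans several decades
  (0.5–30 Hz at 600 Hz).
* The mains "comb" filter is a cascade of RBJ biquad notches at the base
  frequency and all harmonics below Nyquist (default Q = 35, configurable).
* Decoding inputs are *not* 0.5–30 Hz filtered; that band-pass belongs to
  the ERF stage only. The broadband 0.1–100 Hz filter is used for beamformer
  covariance estimation.
* Motion rejection removes trials whose maximum coil displacement (distance
  from the coil position at trial start, maximized over samples and coils)
  exceeds 5 mm; the rule is label-blind, which a test asserts by permuting
  labels.
* GFP is the across-channel standard deviation of the (trial-count
  weighted) grand-average evoked response; the RMS variant is behind a
  flag. Component windows come from the deepest interior local minima of
  the lightly smoothed GFP, with the canonical 60–127/127–173/173–317 ms
  windows as the detection-free default.

# Stimulus tools

Amplitude equalization replaces each image's 2-D Fourier amplitude spectrum
with the set average while keeping its phases; the operation is idempotent
and leaves a set of identical images unchanged. Scrambled (noise) stimuli
combine the average amplitudes with the phase field of white noise, which is
Hermitian-symmetric by construction, so DC and Nyquist bins keep phase
0/π and the inverse transform is exactly real. The GIST spatial-envelope
descriptor uses 4 scales × 4 orientations of one-sided log-Gabor filters
with energies averaged over a 4 × 4 grid (256 values); local-contrast
prefiltering is off by default and available behind a flag. Image-level
control classification (pixels or GIST) uses the same linear SVM with
leave-one-out CV — 30 images are too few for stable 5-fold — with a
resubstitution mode provided as well, since published image-control
analyses often leave the scheme unstated. High-dimensional pixel features
are rotated into the span of the images by thin SVD first; this leaves
every SVM decision value unchanged (the Gram matrix is preserved and the
fit is translation-invariant through the unregularized bias).

# Numerical conventions and degenerate inputs

* SMO duality-gap tolerance $10^{-8}$ for standalone fits, $10^{-6}$ inside
  cross-validation loops; iteration caps raise no error but mark
  `converged = FALSE`.
* Stratified folds: per-class round-robin after a seeded shuffle; without a
  seed the assignment is deterministic in trial order.
* Ties in ROI peak selection: lowest grid index. Zero-variance features
  under standardization: left centered (scale 1). Constant decision
  functions classify balanced resubstitution data at exactly 0.5.
* Permutation nulls are seeded; every user-facing stage takes a `seed`
  argument and the pipeline derives stage seeds deterministically from one
  master seed, so a full run is reproducible bit-for-bit.

# The leakage check

The suite contains a deliberate-contamination experiment: cross-validated
null accuracy with training-fold standardization versus pooled
(train + test) standardization, compared pairwise over 100 null datasets.
The shipped path sits at chance, as required. The contaminated path,
however, is *not* expected to sit above chance: mean/SD scaling is
label-blind, so under the exchangeable null it cannot inject label
information whichever split the statistics come from, and the experiment's
inflation term is correspondingly indistinguishable from zero. The check is
retained because it documents exactly this property; a contamination that
*does* inflate null accuracy would have to involve label-dependent
preprocessing (e.g. feature selection on the full data), which the package
never performs.

# Problem sizes used by the tests

The validation suite runs the full pipeline at desk scale, a deliberate
package choice so that the complete property surface executes in minutes:
16–64 channels, 100–200 Hz sampling over −0.1…0.35 s windows, 40–150
trials per condition, 199 label permutations for calibration runs
(200 null datasets), 20 onset-recovery runs, 50 dipole placements for
beamformer localization (6 mm grid, 64 channels), and 300 replications for
bootstrap coverage. The statistical properties being asserted
(calibration of $(b+1)/(m+1)$ inference, FDR/cluster behavior, unit gain,
localization) are size-invariant; the defaults of `simulation_config()`
and `pipeline_config()` remain at the full experimental scale
(600 Hz, −0.5…1 s, 180 trials, 1000/5000 iterations).

# Known limitations

* Spherical conductor only; no realistic head modeling or coregistration.
* No ICA/regression artifact removal; the motion rule is the only automated
  rejection implemented.
* Sensor-position realignment across subjects is out of scope — synthetic
  subjects share one array by construction.
* Temporal generalization (train at $t_1$, test at $t_2$), multiclass
  decoding and nonlinear kernels are not implemented.
* The epoch container is a documented directory layout (JSON + flat binary
  arrays); FIF interoperability is not provided.
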