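---
title: "Segmentation-free PET/CT survival analysis with multi-angle MIPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-free PET/CT survival analysis with multi-angle MIPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the approach

Outcome prediction for head and neck cancer from FDG-PET/CT conventionally
starts from a manual delineation of the primary tumour and involved lymph
nodes, from which SUV statistics or radiomics features are computed. Manual
segmentation is subjective, slow, and a major source of irreproducibility.
`mamipr` implements a segmentation-free alternative: instead of delineating
lesions, the whole anatomical head-and-neck region is cropped automatically
using bone landmarks visible on CT, and the cropped PET volume is summarised
by image features computed from many maximum intensity projections (MIPs)
taken while rotating the volume about its superior--inferior axis. Those
multi-view features feed a Cox proportional-hazards model evaluated by
repeated nested cross-validation with Harrell's concordance index (c-index).

The pipeline has five stages, each an independently testable module:

1. **Volume I/O** -- NIfTI reading/writing, reorientation into one canonical
   axis order, isotropic resampling, bone-window clipping.
2. **Region cropping** -- bone-window coronal/sagittal CT MIPs, 2D
   head-and-neck boxes (from annotation files or a landmark heuristic),
   combination into a 3D box, PET cropping.
3. **MA-MIP generation** -- the multi-angle MIP stack of the cropped PET.
4. **Deep feature extraction** -- frozen convolutional features per view,
   reduced by one of four global pooling statistics.
5. **Fusion and survival analysis** -- per-patient aggregation of the
   view-feature matrix, then scaling, correlation filtering, ICA reduction,
   Cox fitting and nested cross-validated evaluation.

## Conventions

All volumes use one canonical axis order: x = left--right, y =
anterior--posterior, z = inferior--superior, with voxel centres at
`origin + index * spacing` (mm, 0-based indices). Files in any NIfTI
orientation are permuted/flipped into this order at load time, so every
downstream rotation and projection axis is defined against a single frame.
All boxes are 0-based and half-open, `[lo, hi)`, on every axis.

PET intensities are taken as given (SUV-like); the package does not compute
SUV from raw activity, weight and dose. Whether to normalise PET before
feature extraction is a real design choice, discussed below.

## Cropping by bone landmarks

CT voxels are clipped to the hard-tissue window **700--2000 HU** before
projecting. Clipping uses clamp semantics (both tails saturate) so that bone
appears as a solid bright silhouette in the projections -- the alternative of
flooring out-of-window values to the lower bound is available via
`clip_hu(mode = "floor")`.

The head-and-neck region is defined vertically from the sternoclavicular
joint up to the top of the head and horizontally between the
acromioclavicular joints. When no annotation files are available,
`propose_boxes_heuristic()` recovers this box on phantom-like images from the
bone silhouette alone: the shoulder girdle is the row of maximal
above-threshold width (the most superior such row on ties), the top of the
head is the topmost above-threshold row, and the horizontal extent is the
bone-column span in the upper half of that range, dilated by a margin
(default 8 px). Pixels count as bone when *strictly* above the threshold, so
window-clamped images (where soft tissue saturates at 700) behave correctly.

The two 2D boxes combine into a 3D crop box by taking x from the coronal
box, y from the sagittal box, and z as the **union** of the two vertical
extents. Union rather than intersection is deliberate: the crop must contain
all primary tumours and involved nodes, so over-inclusion is the safer
error; `combine_boxes_3d(z_rule = "intersection")` gives the tighter
alternative. When PET and CT are co-registered but gridded differently, the
box is mapped between grids through physical coordinates
(`map_box_grid()`), never by raw index copying.

## The MA-MIP stack

`generate_ma_mips()` rotates the cropped PET about the z axis in steps of
`step_deg` degrees (default 5, giving 72 views over a full turn) and records
a maximum intensity projection after each rotation. Projection is along the
anterior--posterior axis, so the angle-0 view is exactly the coronal MIP;
the projection axis is a convention of this package, fixed so that the
angle-0 view has a standard radiological reading. Rotation uses bilinear
interpolation about the geometric grid centre with zero fill -- harmless
under a max-projection because the cropped PET background is near zero.
The stage is fully deterministic; regenerating a stack is bit-identical.

Useful invariants (all tested): every view's maximum is bounded by the
volume maximum and the angle-0 view attains it exactly; a 360-degree
rotation reproduces the volume to interpolation accuracy; an axially
symmetric volume yields identical views up to interpolation error.

## Frozen convolutional features

Each view is mapped to a 3-channel square tensor (`prep_for_backbone()`):
intensity scaling to [0, 1], centred zero-padding of the short axis to a
square (aspect-preserving), bilinear resize to the backbone's input size,
channel replication, and channel-wise standardisation with the usual
natural-image constants.

Two intensity scalings are offered, because the right one depends on the
question. Per-image min--max (the default of `prep_for_backbone()`) gives
every view full dynamic range but erases the absolute uptake level -- after
it, a faint and an intense lesion of the same shape look identical. A fixed
window (`intensity_window = c(0, SUVcap)`) preserves absolute intensity
across patients, which matters for survival modelling where uptake level
itself is prognostic. The cohort-level driver
(`extract_cohort_features()`) therefore defaults to a fixed `c(0, 12)`
window, chosen to sit above the phantom generator's lesion peak range
(2--10) with headroom; per-image scaling remains available.

The feature extractor is a registry of three **frozen random-weight
convolutional filter banks** (`small`, `medium`, `large`: 64/96/128-pixel
inputs; 32/48/64 output channels; three 3x3 convolution + ReLU blocks with
2x2 max-pool between blocks). Weights are He-scaled Gaussians drawn once
from a fixed per-backbone seed and cached, so extraction is bit-reproducible
across machines, needs no GPU, no downloads, and is never trained or
fine-tuned -- random convolutional features are a long-standing, surprisingly
strong featurisation baseline, and freezing them keeps the whole pipeline
deterministic. The three scales mirror a small/medium/large model family so
the effect of extractor capacity can be studied. Channel count and input
size are properties of the loaded model; callers never hard-code them. The
registry is the extension point for plugging in other (e.g. pretrained)
extractors behind `extract_feature_tensor()`'s contract: deterministic
pre-classifier activations for a prepared image.

Four global poolings reduce the C x H x W activation tensor to a length-C
vector per view: mean, max, median, and standard deviation. The standard
deviation uses the population (divide-by-N) convention -- it is a descriptive
spatial summary, not an estimator of anything. Stacking the V view vectors
gives the patient's V x C feature matrix.

## Multi-view fusion

Six schemes aggregate the V x C matrix into one vector:

* **Channel-wise statistics** (`cw_mean`, `cw_median`, `cw_max`, `cw_std`):
  per-column view statistics; permutation-invariant over views; no fitting.
* **Per-channel ICA** (`fit_ica_fusion()` / `apply_ica_fusion()`): for each
  channel, a one-component FastICA over the cohort's N x V matrix of that
  channel's view values (patients as observations, views as mixed signals)
  yields a length-V unmixing vector; applying it is a dot product with the
  patient's view column. This is the only reading of "per-column ICA" under
  which a *fitted* model collapses V view values into one number per channel.
  Sign indeterminacy is fixed by non-negative correlation with the
  cross-view mean, scale by unit-norm unmixing vectors; channels that are
  (near-)constant across the cohort bypass ICA with uniform 1/V weights,
  reproducing the constant; channels whose fixed-point iteration does not
  converge fall back to the first principal direction (recorded on the
  model).
* **Autoencoder** (`fit_autoencoder_fusion()`): a single-hidden-layer
  autoencoder (affine encoder/decoder) on the flattened V*C vectors,
  mean-squared reconstruction loss, full-batch Adam (200 epochs, learning
  rate 0.01), seeded initialisation. The default latent width is 32,
  proportionate to the built-in backbones' channel counts (32--64) and to
  cohorts of a few hundred patients; both are configurable.

The fitted schemes (ICA, autoencoder) are estimated **per training fold**
inside cross-validation, never on the full cohort -- fitting them on all
patients would leak test-fold information into the survival evaluation.
Statistical fusions need no fit and are applied up front.

## The survival pipeline

`nested_cv()` evaluates features against right-censored outcomes:

* **Outer loop**: 5 folds (80/20), re-shuffled for each of `n_repeats`
  repetitions (20 in the full protocol). Fold assignment is stratified by
  event status so every training fold contains events.
* **Inner loop**: 5-fold grid search on the outer-training data over the
  ICA component count (default grid 10/20/50, automatically capped at the
  feature count, training rank and N-1), the Cox ridge penalty (0/0.1/1),
  and the correlation threshold (default a single 0.95).
* **Per-fold pipeline**: standard scaling (population SD; zero-variance
  features map to 0), greedy elimination of features with |Pearson r| >=
  threshold against an earlier kept feature, FastICA reduction, Cox
  partial-likelihood fit (optional ridge). Every fitted object is learned on
  outer-training data and applied exactly once to the outer test fold.
* **Scoring**: Harrell's c-index with the standard tie conventions -- a pair
  is comparable when the shorter time is an event, or when times are tied
  with exactly one event; tied risks count 0.5; tied times with two events
  are not comparable.

Because "mean and SD over the five unseen folds" is ambiguous under
repetition, the result reports both: the overall mean/SD across all outer
splits, and a per-repetition 5-fold summary (`$per_repetition`).

Failed splits are recorded with their error message, never silently
dropped. Every split stores the numeric content of its fitted transforms;
`audit_leakage()` re-derives each one from the outer-training rows alone
and compares bit-for-bit, proving the evaluation leakage-free. A fixed
master seed makes the entire procedure deterministic
(`cv_result_json()` output is byte-identical across runs).

### Numerical choices

* FastICA: logcosh nonlinearity, deflation, tolerance 1e-4, 200 iterations
  (the conventional defaults), eigenvalue whitening with a relative rank
  floor of 1e-10. Non-convergent fits are retried with perturbed seeds;
  after that `reduce_ica()` keeps the last orthonormal iterate with a
  warning by default (`on_fail = "error"` restores strict behaviour).
  Near-Gaussian data -- e.g. pure-noise features -- has no unique independent
  directions, so non-convergence there is expected and benign: the iterate
  still spans the whitened subspace.
* Cox: Breslow ties; if an unpenalised fit fails (separation,
  non-convergence) it is retried once with ridge penalty increased by 1.
* Resampling: separable per-axis interpolation (cubic spline for order 3,
  linear for order 1, nearest for 0), output size `floor(extent / target)`,
  edge replication beyond the sampled centres. Order-1 mode provably never
  overshoots the input range; cubic mode may, as splines do.
* Inner grid-search ties resolve to the first (smallest) combination.

## The synthetic phantom family

`phantom_spec()` / `make_phantom_pair()` / `make_cohort()` generate paired
CT/PET volumes with the statistical structure the pipeline assumes, so every
stage is exercisable end to end without patient data. The CT contains a
vertical head/spine bone column topped by a skull blob and a wide thin
shoulder bar, all at 1200 HU (inside the bone window) over 40 HU soft
tissue -- exactly the landmarks the cropping heuristic keys on, with
seed-jittered position and width. The PET contains 1--3 ellipsoidal lesions
(semi-axes 3--8 mm, peaks 2--10 over a 0.2 background, additive Gaussian
noise of SD 0.1) placed inside the head-and-neck region, with quadratic
intensity profiles whose centre voxel attains the nominal peak exactly.

Survival follows a Cox data-generating process with a closed-form oracle:
the per-patient lesion burden `s = log(1 + sum(peak * volume_cm3))` (a
total-lesion-glycolysis-like summary) is standardised across the cohort;
event times are exponential with hazard `h0 * exp(beta * s_std)`
(`h0 = 0.05` per time unit, `beta = 1.5` per SD); censoring is uniform
administrative on `[0, 9/h0]`, numerically calibrated to censor about 20%
of patients. The truth table records `s`, `s_std`, the true linear risk and
the uncensored time, so the concordance of the *true* risk score can always
be computed next to pipeline results.

What the phantoms do **not** emulate: PET physics (attenuation, partial
volume, scanner point-spread), multi-centre scanner variability, anatomical
realism beyond the bone landmarks, and lesions outside the head-and-neck
region. Passing tests on phantoms therefore demonstrates that the machinery
is correct and leakage-free -- not that the method attains any particular
clinical performance.

### What recovery levels to expect

Under this generating process the concordance of the *true* risk score is
itself bounded: for exponential event times, a comparable pair orders
correctly with probability `logistic(beta * |s_i - s_j|)`, which averages to
roughly 0.79 at `beta = 1.5` for a standardised burden (and stays below
~0.80 for any unit-variance burden distribution). The acceptance script
computes this oracle (`oracle_true_risk_cindex`) next to the pipeline's
cross-validated mean; the pipeline lands a few points below its oracle
(feature extraction recovers the burden with R-squared around 0.9, not
perfectly), and no feature set can exceed it by more than sampling noise. A
null cohort (features independent of outcome) stays at chance level, 0.5,
up to cohort-level sampling spread of a few points.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script cohorts use 48 x 48 x 64-voxel
phantoms (head-and-neck crops around 31 x 31 x 43, close to 32^3), 24
MA-MIP views (15-degree steps), the `small` backbone with average pooling,
channel-wise mean fusion, and nested CV reduced to 2 repetitions x 5 outer
folds with a 4/8/16-component, 0/0.1/1-penalty grid -- sizes chosen so a
full end-to-end run of 200 patients completes in a few minutes on one CPU
while preserving every structural property of the full protocol (72 views,
20 repetitions).

## Worked example

```{r example}
library(mamipr)

spec <- phantom_spec()
cohort <- make_cohort(spec, n = 60, seed = 7)

feats <- extract_cohort_features(cohort, step_deg = 15,
                                 backbone_id = "small", pooling = "avg",
                                 fusion = "cw_mean")
res <- nested_cv(feats$features, cohort$records,
                 n_repeats = 2, n_outer = 5, n_inner = 5,
                 grid = list(n_components = c(4, 8), penalty = c(0, 0.1),
                             cor_threshold = 0.95),
                 seed = 1)
print(res)
summary(res)
plot(res)

# the generating process's own ceiling for this cohort:
concordance_index(cohort$records, cohort$truth$risk)

# prove the evaluation used no test-fold information:
audit_leakage(res, feats$features, cohort$records)
```

## Known limitations

* The built-in feature extractors are untrained filter banks; they make the
  pipeline deterministic and self-contained but will underperform
  large-scale pretrained networks on real images. The registry accepts
  alternative extractors behind the same contract.
* The cropping heuristic assumes phantom-like bone geometry (one head
  column, one shoulder bar); on real CT it is a starting point, not a
  detector. Annotation-file ingestion is the supported route for real data.
* Statistical fusion discards view order; the fitted fusions are sensitive
  to it. None of the schemes weights views adaptively.
* Harrell's c-index is reported as the single evaluation metric; no
  calibration, time-dependent AUC, or competing-risk handling.
* DICOM series reading, RTSTRUCT masks and SUV computation from raw
  activity are out of scope; inputs are NIfTI volumes in SUV-like units.
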