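# mamipr

Segmentation-free outcome prediction from head and neck PET/CT, built around
multi-angle maximum intensity projections (MA-MIPs).

## What problem this solves, and for whom

Predicting recurrence-free survival (RFS) for head and neck cancer from
FDG-PET/CT usually requires an expert to delineate the primary tumour and
involved lymph nodes before any SUV or radiomics feature can be computed.
That manual step is slow, subjective and a major reproducibility bottleneck.
`mamipr` is for imaging researchers who want a fully automatic,
deterministic alternative: crop the whole anatomical head-and-neck region
using bone landmarks on CT, summarise the cropped PET with image features
from many rotated projections, and evaluate a survival model with a
leakage-audited, repeated nested cross-validation.

## The method

For each patient with co-registered PET and CT volumes (resampled to 1 mm
isotropic with third-order splines):

1. **Bone-window cropping.** CT voxels are clamped to the bone window
   (700–2000 HU); coronal and sagittal maximum intensity projections show
   the skeleton. A head-and-neck bounding box is placed on each projection —
   vertically from the sternoclavicular joint to the top of the head,
   horizontally between the acromioclavicular joints — either read from
   annotation files (XML/JSON) or proposed by a bone-landmark heuristic.
   The two 2D boxes combine into a 3D box (x from coronal, y from sagittal,
   z from the union of vertical extents) that crops the registered PET.
2. **MA-MIPs.** The cropped PET is rotated about the superior–inferior axis
   in 5° steps; after each rotation a maximum intensity projection is
   captured, giving V = 72 views per patient.
3. **Frozen deep features.** Each view is fed to a frozen convolutional
   feature extractor (three scales: `small`/`medium`/`large`), and the
   pre-classifier activation tensor T ∈ R^{C×H×W} is reduced per channel by
   one of four global poolings — mean, max, median, std — yielding a V × C
   feature matrix per patient.
4. **Multi-view fusion.** The V view-vectors are aggregated into one vector
   by channel-wise statistics (CW-mean/median/max/std), per-channel
   one-component ICA, or a single-hidden-layer autoencoder (the fitted
   schemes are estimated per training fold only).
5. **Survival analysis.** Standard scaling → elimination of features with
   |r| ≥ 0.95 → FastICA dimensionality reduction → Cox proportional hazards
   h(t|x) = h0(t)·exp(βᵀx), inside a nested 5-fold cross-validation (inner
   grid search over component count, ridge penalty, correlation threshold)
   repeated 20 times; performance is Harrell's concordance index over the
   unseen outer folds.

A synthetic phantom module generates paired CT/PET volumes (bone column +
shoulder bar; ellipsoidal hot lesions) and Cox-linked survival cohorts with
a known lesion-burden effect, so the entire pipeline is testable end to end
without access-restricted patient data.

## Worked example

```r
library(mamipr)

spec   <- phantom_spec()                      # 48x48x64 phantoms, beta = 1.5
cohort <- make_cohort(spec, n = 60, seed = 7) # volumes + survival + truth

feats <- extract_cohort_features(cohort, step_deg = 15,
                                 backbone_id = "small", pooling = "avg",
                                 fusion = "cw_mean")
res <- nested_cv(feats$features, cohort$records,
                 n_repeats = 2, n_outer = 5, n_inner = 5,
                 grid = list(n_components = c(4, 8), penalty = c(0, 0.1),
                             cor_threshold = 0.95),
                 seed = 1)
print(res)
#> <mamip_cv> mean c-index 0.778 +/- 0.067 over 10 outer splits (2 reps x 5 folds)

round(concordance_index(cohort$records, cohort$truth$risk), 3)
#> [1] 0.777
audit_leakage(res, feats$features, cohort$records)
#> [1] TRUE
```

Reading: the cross-validated c-index (0.778; 0.5 = random, 1 = perfect
risk ranking) essentially matches the concordance of the *true* generating
risk score on this cohort (0.777) — the image features recover the planted
lesion-burden signal up to that ceiling — and the leakage audit confirms
every fold's preprocessing was a function of its training data alone. On
phantoms these numbers validate the machinery, not clinical performance.

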