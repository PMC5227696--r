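# voxhier

Voxel-wise hierarchical classification of longitudinal brain MRI:
predicting which patients with mild cognitive impairment (MCI) will
convert to Alzheimer's disease (AD) from serial structural scans.

## Who this is for

Neuroimaging researchers who have a cohort of co-registered,
skull-stripped T1 volumes acquired at scheduled visits (baseline, 6, 12,
18, 24, 36, 48 months by default), a binary conversion label per subject,
and — for converters — the visit month at which conversion was recorded.
The package also ships a synthetic longitudinal phantom generator with
ground truth, so the entire pipeline is testable without any clinical
data.

## The method

Each subject contributes, at every brain voxel v, a longitudinal feature
vector f_v = (I₁(v), …, I_T(v)) of intensities across the T scheduled
visits (missed visits are completed by last observation carried forward).
The pipeline is:

1. **Per-voxel classifiers.** A logistic regression classifier
   p = σ(w·x̃ + b) is fit at every masked voxel by full-batch gradient
   descent on the mean cross-entropy J(w, b), using the full longitudinal
   series (post-conversion scans included). Each voxel's *confident
   value* y_v ∈ [0, 1] is its training accuracy.
2. **Voxel selection.** Significant voxels V_s = {v : y_v > t_s}, with
   t_s = 0.65 by default.
3. **Hierarchical ensemble** on pre-conversion data only (scans at least
   6 months before conversion): voxel-level classifiers are re-fit on
   V_s; voxels whose confident value passes a gate t_h (default 0.5) feed
   per-subject confidence images; patch-level classifiers over a
   non-overlapping w×w×w tiling (default w = 5) consume the gated voxel
   posteriors; gated patch posteriors feed one image-level classifier
   whose output is the final conversion probability (label 1 iff
   p ≥ 0.5). By default the upper levels are trained on cross-fitted
   (out-of-fold) posteriors, which keeps the 0.5 decision threshold
   calibrated on new subjects.
4. **Evaluation** by nested stratified cross-validation (10-fold outer
   and inner loops by default) with grids over (t_s, t_h, w), reporting
   ACC, SEN, SPE and AUC.

See the methods vignette (`vignettes/voxhier-methods.Rmd`) for the model,
all defaults, and design rationale.

## Worked example

A complete run on a small synthetic cohort — simulate, select voxels,
train the hierarchy, cross-validate:

```r
library(voxhier)

cfg <- phantom_config(grid_shape = c(16, 16, 16), seed = 1)
sim <- simulate_cohort(cfg, dir = "cohort")       # NIfTI scans + manifest

prep <- prepare_cohort(sim$manifest)              # mask, rescale, LOCF
store_full <- build_feature_matrix(prep$cohort, prep$mask, prep$schedule)
store_pre  <- preconversion_store(store_full)

sel <- select_voxels(store_full, t_s = 0.65)
print(sel)
#> <voxel_selection> 731/1472 voxels selected at t_s=0.65 (N=60, T=7)
print(selection_curve(sel))
#>  0.5 0.55  0.6 0.65
#> 1460 1399 1133  731
truth_dice(sel, sim$truth)
#> [1] 0.598

model <- train_hierarchy(store_pre, sel, t_h = 0.5, w = 5,
                         store_full = store_full)
print(model)
#> <hierarchical_model> t_h=0.50, w=5
#>   voxels: 731 selected -> 640 gated
#>   patches: 27 non-empty -> 27 gated
#>   image-level training accuracy: 0.983

rep <- nested_cv(store_full, store_pre,
                 grids = list(t_s = 0.65, t_h = 0.5, w = 5),
                 outer_k = 5, seed = 1)
print(rep)
#> <evaluation_report> 5 folds (seed 1)
#>   fold means : ACC 0.783  SEN 0.967  SPE 0.600  AUC 0.928
#>   pooled     : ACC 0.783  SEN 0.967  SPE 0.600  AUC 0.933
```

Reading the output: 731 of 1472 brain voxels exceed the selection
threshold, and the selected set overlaps the implanted atrophy mask with
a Dice coefficient of 0.60 — the selection step recovers the planted
signal plus the optimistic fringe inherent to in-sample training accuracy
at N = 60. Five-fold cross-validation at the default operating point
classifies 78% of held-out subjects correctly on this small 16³ cohort,
with high sensitivity (97% of converters caught) and an AUC of 0.93;
larger grids (32³) reach ACC above 0.9 at the same settings.

A thin command-line front end wraps the same functions
(`inst/cli/voxhier.R`): `simulate`, `train`, `predict`, `evaluate`.

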