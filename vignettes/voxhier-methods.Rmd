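---
title: "Predicting MCI-to-AD conversion from longitudinal MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MCI-to-AD conversion from longitudinal MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Roughly half of patients with mild cognitive impairment (MCI) progress to
Alzheimer's disease (AD) within a few years; the other half remain stable.
Structural MRI captures the atrophy that accompanies progression, and
serial scans capture its *trajectory*, which is more informative than any
single visit. `voxhier` implements a voxel-wise, hierarchical approach to
this two-class problem (converter MCIc vs non-converter MCInc):

1. every brain voxel gets its own small logistic regression classifier
   (LRC) trained on the subject's longitudinal intensity trajectory at
   that voxel;
2. voxels whose classifier separates the training cohort well are
   *selected*;
3. the selected voxels are combined through a three-level ensemble —
   voxel posteriors feed patch-level classifiers over a non-overlapping
   w×w×w tiling of the grid, patch posteriors feed one image-level
   classifier whose output is the final decision.

The package assumes its inputs are already skull-stripped and
co-registered to a common grid; bias-field correction and spatial
normalization are upstream, out-of-scope steps.

## Data model and preprocessing

**Schedule.** The default visit schedule is baseline plus follow-ups at
6, 12, 18, 24, 36 and 48 months (T = 7 time points). Published accounts
of this design vary between six and seven prediction time points; we
default to the seven-visit table and make the schedule fully
configurable, since nothing downstream depends on its length.

**Intensity rescaling.** Within the brain mask, each image is linearly
mapped so its 0.1% intensity quantile goes to 0 and its 99.9% quantile to
100, then clipped to [0, 100]. A constant image rescales to zeros with a
warning.

**Missing visits.** Longitudinal cohorts always have missed visits. Every
absent visit is filled with the most recent earlier scan (last
observation carried forward, LOCF): a subject scanned at months 0, 6, 24
and 36 uses the month-6 scan as month-12 data and the month-36 scan as
month-48 data. We generalize the published two-gap example to strict
LOCF from the nearest earlier visit; the baseline scan is required, so
the rule is total. LOCF is idempotent and keeps T identical across
subjects, which the per-voxel classifiers need.

**Pre-conversion filtering.** When *predicting*, only scans at least 6
months before a converter's recorded conversion month are legitimately
available. `filter_preconversion()` retains visits with month ≤
(conversion month − 6) and carries the last eligible scan forward so the
series keeps length T (the baseline is always retained; non-converters
are untouched). Voxel *selection*, by contrast, deliberately uses the
full series including post-conversion scans, which carry the strongest
conversion signature — this matches the published protocol, where
selection is a training-time step.

**Brain mask.** A voxel is in the mask when it is nonzero in at least
half the cohort's baseline images. Skull-stripped input makes this a
reasonable default; the fraction is configurable.

## The logistic classifier

Each classifier minimizes the mean binary cross-entropy
J(w, b) = (1/N) Σᵢ [−Lᵢ log pᵢ − (1−Lᵢ) log(1−pᵢ)],
pᵢ = σ(w·x̃ᵢ + b), by full-batch gradient descent from a zero start.
Numerical choices:

* features are standardized per column with the training mean and SD
  (zero-variance columns get unit scale) — this makes one learning rate
  (default 0.1) work across voxels with different intensity scales;
* descent stops when the relative cost decrease falls below `tol`
  (default 1e-6) or after `max_iter` (default 500) updates; the cost
  trace is monotone non-increasing at these settings;
* probabilities are clipped to [1e-12, 1 − 1e-12] inside the loss;
* an optional ridge penalty `l2` (default 0) is available; the package
  treats unregularized descent as the canonical fit;
* the hard decision is 1 (converter) iff p ≥ 0.5 — the tie goes to the
  positive class, uniformly everywhere probabilities are thresholded.

A compiled implementation fits tens of thousands of voxel classifiers per
cross-validation fold; an R reference implementation of the identical
algorithm backs it in the test suite. Voxels whose features are constant
at every time point are not fit: they receive the majority-class
confident value, and a bias-only model so downstream posterior calls stay
defined.

## Confident values and voxel selection

The *confident value* y_v of a voxel's classifier is its training
accuracy — the fraction of training subjects whose hard decision matches
the label, always a multiple of 1/N in [0, 1]. (The alternative reading,
an aggregate of per-subject posteriors, is isolated behind the single
`confident_value()` operation and could be swapped without touching
anything else.) Significant voxels are those with y_v strictly above t_s;
the default t_s = 0.65 comes from the published parameter table, and the
selection curve over the grid {0.5, 0.55, 0.6, 0.65} is computed by
re-thresholding only, so selected sets shrink by exact containment.

In-sample accuracy at desk-scale cohort sizes (N ≈ 50–60) is optimistic:
a 7-feature logistic fit on pure noise exceeds 0.65 training accuracy for
roughly a third of voxels. Selection at t_s = 0.65 therefore admits a
winner's-curse fringe around the true signal; this is a property of the
published selection rule, not a defect of the implementation, and the
hierarchy's stacking (below) is designed to cope with it.

## The hierarchy and cross-fitted stacking

`train_hierarchy()` builds, on pre-conversion features restricted to the
selected voxels:

1. **voxel level** — one LRC per selected voxel; voxels whose confident
   value reaches the gate t_h are kept (unit gating: a voxel is kept for
   all subjects or dropped for all — the only reading under which the
   upper levels see fixed-dimension inputs);
2. **confidence image** — per subject, a map on the original grid with
   gated voxels' posteriors and exact zeros elsewhere;
3. **patch level** — one LRC per non-empty w×w×w block of the
   origin-anchored, edge-truncated tiling (default w = 5), fed the
   subject posteriors at the block's gated voxels; blocks reaching t_h
   are kept;
4. **image level** — one LRC on the kept blocks' posteriors; its output
   is the final decision.

The gate threshold t_h (default 0.5) is shared across levels, and units
*below* t_h are discarded — so t_h = 0 keeps everything, and raising t_h
never enlarges a level. Voxels within a block and blocks within the image
are ordered lexicographically by coordinate and the ordering is recorded
in the model.

**Why cross-fitted stacking is the default.** Trained on its own
training posteriors (in-sample stacking), the ensemble mis-calibrates
badly: held-out voxel posteriors shrink toward 0.5 relative to the
overfit training posteriors, the steep patch and image classifiers
amplify the shift, and every held-out subject lands above the 0.5
decision threshold — ranking survives (AUC near 1) while accuracy drops
to chance. The default `stack = "crossfit"` therefore trains each upper
level on *out-of-fold* posteriors from the level below (default 5
cross-fit folds, stratified):

* for each cross-fit fold, voxel classifiers **and selection
  confidences** are recomputed without that fold's subjects; a fold's
  subjects receive honest posteriors at voxels that would still have been
  selected without them, and an uninformative 0.5 at voxels whose
  selection depended on them — without this, the winner's-curse fringe
  keeps its spurious separation in every training row (all training
  subjects took part in selection) and the upper levels learn to rely on
  it;
* under cross-fitting, t_h gates on *out-of-fold* accuracy rather than
  training accuracy. Training accuracy is ≥ 0.5 almost surely, which
  makes the published gate a no-op; out-of-fold accuracy lets t_h = 0.5
  discard genuinely useless voxels and patches, consistent with the
  published observation that gating at 0.5 beats no gating.

`stack = "insample"` retains the literal reading (training posteriors,
training-accuracy gates) for comparison. The deployed model always
consists of full-training-data classifiers at every level; cross-fitting
only changes what the upper levels are trained *on*.

**Single global baseline.** `fit_single_global()` fits one LRC on the
concatenation of all selected voxels' longitudinal features (dimension
|V_s|·T), the flat alternative the hierarchy is compared against.

## Evaluation

`nested_cv()` runs two nested stratified k-fold loops (defaults 10/10).
Folds deal each class round-robin after a seeded per-class permutation,
so class proportions match within one subject; a 70/61 cohort at k = 10
gives folds of 13–14 subjects with 7 converters and 6–7 non-converters.
For each outer fold, the inner loop scores every (t_s, t_h, w) grid point
by mean validation accuracy — default grids t_s ∈ {0.5, 0.55, 0.6, 0.65},
t_h ∈ {0, 0.5, 0.55, 0.6, 0.65}, w ∈ {1, 3, 5, 7, 9, 11} — the winner
(ties towards the smallest t_s, then t_h, then w, favoring sparser
models) is refit on the whole training portion and applied to the
held-out fold. Selection always sees only the fold's training subjects;
validation and testing use pre-conversion data. Confident values are
computed once per inner split and re-thresholded across the grid, so the
grid search costs little more than a single point. With singleton grids
the inner loop is skipped entirely.

Metrics are accuracy, sensitivity (converter recall), specificity
(non-converter recall), and AUC computed as the rank-based Mann–Whitney
statistic (ties rank-averaged), which equals the trapezoidal area under
the empirical ROC. Per-fold metrics and their means are reported; AUC is
additionally computed on probabilities pooled across outer test folds,
since fold-wise AUC on a dozen subjects is coarse. Reports are
reproducible bit-for-bit given (cohort, seed, grids, config).

`compare_conditions()` runs {longitudinal, baseline-only} × {hierarchy,
single global} on one shared fold plan for paired comparisons; the
baseline-only conditions rebuild T = 1 stores from the baseline scan for
both selection and classification.

## The synthetic phantom

`simulate_cohort()` generates the cohort the classifier assumes, with
ground truth:

* a shared template: smoothed Gaussian random field scaled to [20, 80]
  inside a spherical brain (zero outside), with a dark CSF-like rim and a
  bright white-matter-like core — these dense populations at both
  intensity extremes pin the 0.1%/99.9% rescaling quantiles, so the
  implanted atrophy cannot shift the per-image rescaling map and thereby
  leak into out-of-region voxels (without the anchors we observed exactly
  this leak: null-voxel selections grew with effect size);
* two ellipsoidal signal regions (~20% of the brain together, a coarse
  proxy for distributed medial-temporal plus temporoparietal atrophy),
  whose template intensities sit in a homogeneous mid band [56, 58],
  several noise SDs away from either quantile anchor at every progression
  stage;
* converters' signal-region intensities decrease linearly from 0 at
  baseline to Δ·σ at the subject's conversion month and stay decreased —
  Δ (default 2) is the effect size in units of the noise SD σ (default 5
  on the [0, 100] scale); non-converters are stationary;
* smooth subject-level template perturbations (SD 2 intensity units), a
  modest anatomy proxy;
* conversion months drawn from the schedule's follow-up visits with
  probabilities proportional to the published conversion-timing counts
  (11, 28, 17, 7, 7 over months 6–36); class sizes default to 30/30;
* i.i.d. Gaussian noise everywhere in the brain; each follow-up visit is
  missed independently with probability 0.1 (never the baseline).

Baseline intensities carry no class signal — the discriminative
information is purely longitudinal-progressive, matching the method's
premise. The generator is deterministic given its seed and writes the
same NIfTI + manifest formats the package consumes.

What the phantom does *not* emulate: anatomical realism, scanner
artifacts, spatially correlated noise, registration error, and
heterogeneous per-subject atrophy patterns. Passing tests on phantoms
shows the pipeline recovers planted, spatially clustered, class-linked
longitudinal change at realistic noise levels — not that it attains any
particular accuracy on clinical data.

## Problem sizes and what the checks show

Whole-suite runs use desk-scale sizes chosen once: recovery and
discrimination checks on the 32³ default grid (≈11,600 brain voxels,
N = 60, outer 5-fold CV at the default operating point), and the paired
design comparisons on 16³ phantoms with 5 seeds. At these sizes the suite
verifies, among others: exact containment of selected-voxel sets along
the t_s grid; Dice ≥ 0.5 between the selected set and the implanted mask
at Δ = 1.5; cross-validated accuracy ≥ 0.9 at Δ = 2 with collapse to
chance under label permutation; and a large paired advantage of
longitudinal over baseline-only data.

## Known limitations

* **Hierarchy vs single classifier at desk scale.** On these phantoms
  the flat classifier on |V_s|·T standardized features is close to the
  matched filter — homogeneous signal plus i.i.d. noise is exactly the
  regime where global pooling is optimal — and it edges out the hierarchy
  by a few accuracy points, while the hierarchy matches or beats it on
  AUC. The published advantage of the hierarchy arises in the megavoxel,
  subtle, spatially heterogeneous clinical regime that a ≤32³ phantom
  cannot reach. The comparison harness reproduces the experimental
  design; it should not be read as a verdict on either architecture.
* **Residual calibration bias.** Training rows participated in voxel
  selection and new subjects did not; cross-fitting removes most but not
  all of the resulting shift (the last fraction is a conditioning
  difference no refitting scheme inside the published architecture can
  remove), so the hierarchy's held-out decisions retain a slight
  converter bias at small N.
* **In-sample confident values** are optimistic by construction; t_s is
  best understood as a rank filter, not an accuracy estimate.
* LOCF imputation and pre-conversion carry-forward make converters'
  series flatter, which is itself label-correlated structure; it is part
  of the published data model, and the phantom reproduces it.
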