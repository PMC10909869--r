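---
title: "Methods: multi-modal CNN classification and Grad-CAM attribution on synthetic neuroimaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal CNN classification and Grad-CAM attribution on synthetic neuroimaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`neurofuse` implements a complete binary-classification pipeline for paired
structural MRI and amyloid PET brain volumes: longitudinal diagnosis-label
curation, brain-extraction preprocessing, eight convolutional-network
variants (2D/3D, uni-modal, transfer, combined-input, and dual-branch
fusion), diagnostic metrics, and Grad-CAM-based attribution of the model's
evidence to atlas regions. Because the clinical cohorts this kind of
analysis runs on are access-controlled, the package ships a first-class
synthetic-data module that generates cohorts with *known planted signal*,
so that every downstream stage — including the claim that fusing two
modalities beats either alone — is a testable property rather than an
anecdote.

## The synthetic cohort generator

`make_toy_atlas()` builds an ellipsoidal brain mask on a voxel grid
(default desk scale: 32×32×32) and partitions it into `n_regions`
connected regions by multi-source region growing from random seed voxels
(a discrete geodesic Voronoi partition; regions are 6-connected by
construction). Each region receives a baseline intensity drawn once from
N(20, 1).

Three deliberate phantom-design choices:

* **Near-homogeneous baselines** (`baseline_sd = 1`, the voxel-noise
  unit). Grad-CAM's spatial localization comes from the activation maps'
  brightness pattern; if baseline anatomy contrast is large compared to
  the planted effect, the brightest *unaffected* region outshines the
  planted one at every convolutional stage and region recovery measures
  anatomy, not evidence. A localization phantom plants a hot spot on a
  near-uniform background; baseline variation is kept at the noise scale
  so the atlas still has non-trivial structure.
* **Hot-spot contrast** (`baseline_mean = 5` in the reference study, so
  tissue:background is 5:1 over unit noise and the planted lesion is
  roughly 2:1 against tissue — the contrast regime of standard hot-sphere
  phantoms). Early convolutional channels respond most strongly to the
  tissue/background boundary; if the planted effect is a small fractional
  change of a bright baseline, boundary responses dominate every
  relevance map. A 2:1 lesion keeps the planted signal competitive with
  edge responses while Otsu brain extraction still separates tissue from
  background comfortably.
* **Between-subject variability** (`between_subject_sd = 1`). Each volume
  receives one scalar intensity shift in its modality's affected regions,
  drawn per volume and *independent of class*. Without it, region-averaged
  SNR grows with the voxel count of the region and every model variant
  saturates at accuracy 1.0, which would make "fusion beats uni-modal" an
  untestable tie. With it, a single modality has irreducible class overlap
  (disease effect vs. individual variation), while two modalities carry
  independent evidence that fusion can combine.

`effect_spec()` fixes, per modality, the affected regions (defaults:
region 2 for MRI, region 7 for PET — disjoint, so the modalities are
complementary by construction), the additive effect size (default 5, i.e.
effect/noise = 5), voxel noise (1), and for PET the number of time frames
(4; each frame is an independently noised copy of the 3D target, so frame
averaging denoises and reproduces the target exactly in the noise-free
case).

`simulate_timeline()` produces per-subject visit days with strictly
increasing gaps and a monotone disease path (negative subjects stay
negative; positive subjects convert at a random visit), plus independent
label flips at `flip_prob` — the recording noise the label-correction
algorithm is designed to undo. Scans are always generated from the *true*
disease state; only the diagnosis events carry flips.

What the generator does **not** emulate: anatomy, partial-volume effects,
scanner physics, registration error, or any spatial correlation in the
noise. Passing tests therefore demonstrate the correctness and the
statistical behaviour of the pipeline's machinery, not clinical
performance on real scans.

## Label curation

`correct_labels()` repairs isolated flips in one subject's time-ordered
diagnosis sequence using a two-before/two-after neighbourhood rule: a
negative with at least one positive among its up-to-two predecessors *and*
at least one among its up-to-two successors becomes positive; the
symmetric rule turns a spuriously positive event negative. The
implementation applies the false-negative repair first (simultaneously,
on the original labels) and the false-positive repair second (on the
repaired sequence). Each phase is simultaneous, hence order-independent
and deterministic; repairing false negatives first prevents an isolated
negative gap inside a positive run from erasing its true-positive
neighbours. Boundary events (with no neighbour on one side) are never
corrected. The test suite checks this against an independently written
brute-force oracle on *all* label sequences of length ≤ 6.

`assign_scan_label()` links each scan to the temporally closest corrected
diagnosis, before or after the scan; exact ties go to the earlier event (a
deterministic convention). `drop_repeat_positives()` keeps only the
earliest positive scan of each consecutive positive run, per subject and
modality. Class balancing uses `undersample_negatives()` (uniform, seeded)
and `augment_positives()` (compositions of in-plane 90° rotations and
left–right mirroring — rigid voxel permutations, so augmentation is
lossless and each augmented record is tagged with its source and
transform). Augmentation is applied after the patient-wise split and only
to training data, so no augmented copy of a test subject's scan can leak
into training.

`patient_wise_split()` partitions subjects, never scans
(`round(test_fraction × n_subjects)` test subjects, at least 1), and
`stratified_folds()` assigns subjects to k folds with per-fold class
counts within one subject of proportionality.

## Preprocessing

Raw 4D PET is reduced by `average_frames()` (arithmetic mean over time).
Brain extraction runs per axial slice: a 13×13 Gaussian blur with
sigma = 150 — so wide relative to its support that the truncated,
renormalized kernel is uniform to within 0.1%, effectively a box smoother;
it is applied exactly as specified — followed by Otsu's threshold (256
bins over the slice's intensity range, ties broken toward the lower
threshold) computed on the *blurred* slice. The above-threshold mask is
evaluated on the original slice, so a crisp phantom yields exactly its own
extent. The tightest 3D half-open box containing all above-threshold
voxels is cropped, each axial slice is resized in-plane by bilinear
interpolation (half-pixel-centre convention; no resampling along the slice
axis), and the central `n_slices` are kept (centre biased low for odd
remainders). Intensity normalization is configurable: the default maps
the pooled training-cohort range to [0, 1] with *one* affine map (reused
unchanged for validation and test scans). Per-volume min–max is also
available; it compensates arbitrary per-scan gain but couples every voxel
to the volume's extremes — an additive regional effect then also shifts
all other voxels after scaling, turning local class evidence into a
global contrast change that blurs attribution, which is why the shared
map is the default for the synthetic study. Desk-scale configuration:
32×32 in-plane, 12 slices; the full-scale 128×128×50 path is the same
code with different parameters. The preprocessing geometry
(box, retained slices) is recorded on each output so relevance maps can be
mapped back into the original atlas grid.

## Models and training

All variants share a feature block of four stages — 3×3(×3) convolution →
ReLU → 2× max-pool → batch normalization — with strictly increasing filter
counts, then flatten → dense stack → 30% dropout → 1-unit sigmoid. Desk
preset: 4→8→16→32 filters and one 32-unit dense layer; full-scale preset:
16→32→64→128 and 128. Max-pooling uses ceil-mode windows so that the
12-slice desk volumes survive four pooling stages (12→6→3→2→1). The
fusion variant builds two *independent* (non-weight-shared) branches whose
flattened features are concatenated before the classifier; the
combined-input variant is a single branch trained on batches drawn
alternately from the MRI and PET streams (per batch, recycling the
shorter stream); the transfer variants freeze the entire feature block —
parameters and batch-norm statistics, verified bit-exact by checksum —
and retrain only the classifier.

The network stack (im2col convolution via BLAS matrix products, exact
backpropagation, Adam) is implemented in the package; the test suite
verifies every gradient against central finite differences.

Training uses binary cross-entropy
`-(y log ŷ + (1-y) log(1-ŷ))`, Adam with learning rate
`lr0 · 0.96^epoch`, early stopping when the monitored validation metric
has not improved for `patience` epochs, restoring the best epoch's
weights. Full-scale defaults are lr0 = 5e-5, patience 35, up to 10,000
epochs, monitoring validation *accuracy*; the desk preset uses lr0 = 1e-3
(Adam's conventional default, appropriate for the small desk networks and
few epochs), patience 12, at most 60 epochs, batch size 8, and monitors
validation *loss* — with a ~10-scan validation carve-out, accuracy moves
in steps of 0.1 and the best-accuracy epoch is frequently a lucky,
undertrained one (restoring it can even produce below-chance held-out
accuracy); the continuous cross-entropy identifies the genuinely best
epoch. Decay is applied per epoch; the classification threshold is
0.5. Every stochastic element (initialization, shuffling, dropout) sits
inside one seeded stream, so a training run is a pure function of its
configuration.

## Grad-CAM and region attribution

For a chosen convolutional stage with feature maps `A^k`, the neuron
importance weights are the spatially pooled gradients
`alpha_k = (1/Z) * sum_ij d(score)/dA^k_ij` (for 3D models the pool runs
over all three axes and Z is the voxel count), and the relevance map is
`L = ReLU(sum_k alpha_k A^k)`. The score is the pre-sigmoid logit (its
negation for the negative class): the logit is linear in the evidence, so
the map scales covariantly with the logit, which the tests check. `A` is
taken post-ReLU, before pooling; the default stage is the last
convolutional stage, standard Grad-CAM practice. For fusion models each
branch yields its own map, mirroring per-modality attribution tables.

Maps are upsampled to input resolution (trilinear), mapped back into the
original voxel grid by inverting the recorded crop/resize/slice-selection
geometry (voxels outside the preprocessed field of view get zero
relevance and are marked in a coverage mask), and averaged over all scans
of a group (a flag restricts to correctly classified scans).
`region_attribution()` averages relevance over each atlas region and
selects regions at or above the 90th percentile of region means (ties
included). When a coverage mask is available, each region's mean is taken
over its covered voxels only — otherwise partially seen regions are
diluted by structurally-zero voxels — and regions with less than half
their voxels in the field of view are excluded from ranking: a small
covered fragment of a mostly-unseen region is a high-variance mean that
cannot be compared fairly with fully observed regions (empirically, such
fragments sitting on slab-edge cells of the coarse map win rankings by
artifact). Group attribution reports both the selection on the group-mean
map and the per-scan selection frequency of each region.

One resolution caveat drives a desk-scale choice: on a 32-voxel grid the
last stage's spatial grid is 2×2×1 — coarser than the 10-region
parcellation being scored — so the package's reference recovery
experiment (`check_region_recovery()`) uses stage 2 (8×8×3), the deepest
stage that still resolves the parcellation. `gradcam()`'s own default
remains the last stage.

## Evaluation

Accuracy, sensitivity (true-positive rate) and specificity (true-negative
rate) come from confusion counts at threshold 0.5; metrics with empty
denominators are reported as undefined (`NA`), never 0. AUC is the exact
tie-aware rank statistic (probability a random positive outscores a random
negative, ties ½), which the tests verify equals trapezoidal integration
of the empirical ROC. For 2D variants, slice predictions can be aggregated
per scan by mean probability (default) or majority vote. Result tables are
sorted by ascending accuracy and rounded only at display time.

## Reference experiments and problem sizes

`study_conditions()` / `build_study_data()` / `run_variant()` wrap the
package's reference experiment: 60 subjects, two visits each (one-visit
override for the single-scan recovery design), 32³ grid, 10 regions,
effect/noise = 5, patient-wise 80/20 split with a further 20% validation
carve-out, desk architecture and training preset. Two visits also give a
24-scan held-out set, so accuracy medians across seeds resolve at 1/24
rather than 1/12 — important when comparing model variants whose true
accuracies differ by less than one test subject. The
planted regions default to the two most axially central regions of the
generated atlas (MRI in the most central, PET in the second): the model
only sees the central slices, so the lesion is planted where the model
looks — standard phantom practice; an arbitrary region id can land a
region with a sliver of slice coverage that no attribution method could
recover.

The recovery experiment (`check_region_recovery()`) accepts an ensemble
of models trained on the same data with different training seeds and
averages their atlas-space group maps before region scoring. The
relevance maps of networks this small carry substantial
training-trajectory noise — which region narrowly tops the ranking can
depend on the weight initialization — while the planted-region component
is what independently trained models share, so a 3-model average raises
single-run recovery substantially at proportional compute cost. On one
CPU a uni-modal 3D run takes about a minute; the complementarity
experiment (effect halved to 2.5, MRI/PET regions disjoint) trains the
two uni-modal models and the fusion model over five seeds and compares
median held-out accuracies. The experiments cap epochs at 40 (recovery)
and 25 with patience 5 (complementarity) — the loss-monitored early
stopping typically fires between epochs 15 and 30, so the caps mostly
trim non-converging stragglers. These sizes are the package's chosen
desk-scale study design; the same functions accept larger grids, deeper
architectures and longer schedules.

## Known limitations

* The synthetic phantom is additive and spatially uncorrelated; it cannot
  certify performance on real anatomy.
* Grad-CAM at desk scale is resolution-limited (see above); attribution
  statements are at the region level, not voxel level.
* The 2D variants treat slices independently; their slice-level metrics
  are optimistic relative to scan-level aggregation when slices of one
  scan disagree.
* Batch normalization uses batch statistics during training; with batch
  size 8 the running statistics used at inference converge only after a
  few epochs, which is visible as early-epoch validation noise.
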