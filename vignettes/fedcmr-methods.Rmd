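---
title: "Simulating federated multi-center cardiac MRI diagnosis with fedcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating federated multi-center cardiac MRI diagnosis with fedcmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedcmr)
```

## The problem

Deep-learning diagnosis models for cardiovascular magnetic resonance (CMR)
are usually trained and evaluated on single-center data, which leaves two
questions open: how well do they transfer to centers never seen during
training (the non-IID problem), and can multiple centers collaborate
without sharing patient images? `fedcmr` implements a desk-scale simulation
of a multi-center study of hypertrophic cardiomyopathy (HCM) versus normal
(NOR) diagnosis that addresses both questions jointly: four simulated
acquisition sites, privacy-preserving intensity harmonization, three
collaborative training frameworks, and two cross-validation geometries that
separately estimate in-site and out-of-site performance.

Everything runs from synthetic cardiac phantoms, so the full pipeline is
testable on one CPU with no external data.

## The synthetic cohort

`generate_cohort()` draws one cardiac geometry per subject;
`render_phantom()` voxelizes it at a center's native spacing. The phantom
is deliberately the simplest geometry that makes the downstream analysis
meaningful:

* an axis-aligned ellipsoidal LV blood pool (mask label 1) inside a
  concentric myocardial shell (label 2), plus a crescent-shaped RV blood
  pool (label 3) — the three structures a short-axis segmentation
  delineates;
* two timepoints per subject: end-systole contracts the cavity radii
  (ES/ED ratio uniform on 0.60–0.75) and thickens the wall (ratio
  1.25–1.40), so ED and ES are genuinely different samples of one subject;
* disease encoding through geometry: NOR end-diastolic wall thickness is
  drawn from a truncated normal on 6–11 mm, HCM from 17–26 mm. The 15 mm
  clinical rule for hypertrophy sits inside the gap, and
  `measure_wall_thickness()` (a per-slice exact Euclidean distance
  transform; thickness = 4 x median boundary distance, with a half-voxel
  correction) verifies the encoding on the rendered masks. The gap makes
  the default task *easy by construction*: recovery tests need
  above-chance learning at desk scale, and the truncation bounds are a
  config knob (`geometry_config()`) for harder regimes.

Center differences follow what makes multi-site MRI non-IID: native voxel
spacing and slice thickness (resampling artifacts), additive intensity
offset, multiplicative gain, Gaussian noise, and a smooth multiplicative
bias field (a low-frequency cosine bump, the kind of artifact N4-style
correction removes). The default four centers reproduce the published
NOR/HCM counts of the study cohort (21/25, 33/37, 14/10, 20/20; 180
subjects) with spacings inside each center's published ranges. The
*magnitudes* of the intensity differences are free parameters — the source
study shows them only as qualitative histograms — chosen once so that the
inter-center histogram shift is clearly visible before harmonization and
mostly gone after it.

What the generator does **not** emulate: anatomical variability beyond two
ellipsoid parameters, papillary muscles, trabeculation, partial-volume
effects, motion, or realistic MR noise correlation. A passing recovery test
therefore shows that the *pipeline* (preprocessing, harmonization,
federation, evaluation) behaves correctly, not that the classifier would
reach any particular accuracy on real CMR.

Randomness is organized as one master seed from which per-center and
per-subject streams are derived, so any volume can be re-rendered
bit-identically regardless of generation order.

## Preprocessing and induced shape priors

The chain is `bias_field_correct()` → `resample_isotropic()` (to 1x1x1 mm)
→ `crop_to_window()` (150x150x10 voxels, centered on the segmentation's
bounding box) → `curate()`.

Numerical choices, where the underlying study is silent:

* *Bias correction.* N4 itself is cited, not contributed, by the study, so
  the contract here is only bias reduction: log intensities of segmented
  voxels are modeled as structure-specific means plus a degree-2 polynomial
  in the voxel coordinates (the segmentation plays the role of N4's mask
  and tissue model); the exponentiated polynomial, normalized to unit mean,
  is divided out. On phantoms with a known 20% bias bump this cuts the
  within-structure coefficient of variation by an order of magnitude, and
  on bias-free volumes it is a near-exact no-op.
* *Interpolation.* Trilinear for images, nearest-neighbor for masks (label
  sets must survive exactly).
* *Cropping.* The window start is `center - floor((window - 1)/2)` with the
  bounding-box center at the floor of the midpoint (0-based), which makes
  the crop of an exactly window-sized mask the identity; out-of-grid
  regions are zero-padded so the output shape is always exactly 150x150x10.

Curation induces the shape priors: `baseline` replicates the image to three
identical channels (the 3-channel input shape comes from the pretrained
video backbone), `masked` multiplies by the binary segmentation first, and
`per_structure` gives each structure its own channel in the order (LV blood
pool, RV blood pool, myocardium) — the channels then have pairwise disjoint
support, and their sum reproduces the masked image. ED and ES are emitted
as separate training samples that must never be split across partitions.

## Privacy-preserving harmonization

Each center reduces its images to one `histogram_aggregate` on a shared
256-bin grid spanning a robust range (0.5th–99.5th percentile, outliers
clipped); per-subject histograms are normalized to unit mass before
aggregation so every image counts equally regardless of voxel count. Only
these aggregates cross center boundaries.

The matching reference is the mean per-sample histogram
`(1/N) * sum_k sum_n H_n^k`. The study's printed formula applies an
additional `N_k/N` factor to the inner sum, which would double-weight large
centers if the inner sum is read as an unnormalized total; we adopt the
per-sample mean, which matches the accompanying prose ("the average
histogram of all images") and reduces to the obvious answer for one
center. `fit_standardization()` then performs Nyul-style matching —
monotone piecewise-linear interpolation between landmark percentiles
(deciles plus the 1st/99th), linear extrapolation at the tails — followed
by a min–max rescale to [0, 1] on the masked support. Under
leave-center-out evaluation the reference excludes the held-out center, so
its subjects are matched to a reference they did not shape.

Masked-value histograms are used whenever curation uses the mask
(`masked`, `per_structure`); the `baseline` curation uses full-window
histograms.

## Augmentation

Four nested pools, applied with probability 0.5 (one transform drawn
uniformly per application, never a composition): `basic` = axial rotation
(default +/-15 degrees; the study does not quantify "varying degrees") and
horizontal/vertical flips; `shape` adds a low-scale elastic deformation
(coarse 4x4 control grid, 2-voxel displacement SD); `shape_intensity` adds
a k-space-spike stripe artifact, a random multiplicative bias field,
Gaussian noise with sigma ~ U(0, 0.25) on the [0, 1] scale, and random
gamma. Spatial transforms use nearest-neighbor resampling for
per-structure inputs — this preserves the disjoint-support invariant
exactly, which bilinear interpolation would violate at structure
boundaries — and bilinear resampling otherwise.

## Classifiers

`build_classifier()` constructs either architecture behind one interface:

* `resnet3d_18`: the Tran et al. 3D ResNet-18 ("R3D") with its
  classification head replaced by a newly initialized 512-input,
  single-logit linear layer with bias. The layout reproduces the published
  parameter budget exactly — 33,166,785 parameters in total, of which the
  512 head weights (plus one bias) are trainable when the backbone is
  frozen. Pretrained video weights are an optional external asset behind a
  loader hook; requesting them without a weights file is an explicit error,
  never a silent random fallback.
* `small3d`: the desk-scale workhorse. A frozen random convolutional
  backbone (5x5x2 average-pool downsampling, an 8-filter 3x3x3
  convolution, ReLU, 3x3x1 adaptive average pooling) plus a
  pooled-intensity skip branch (the per-channel means, which under mask
  curation carry structure-volume information directly), scaled by a fixed
  gain of 8 so features are O(1) under the default head learning rate of
  0.01 — pooled activations of [0, 1]-rescaled inputs are otherwise O(1e-2)
  and the head would barely move within a short round budget. A logistic
  head on these 75 features trains in milliseconds.

Both use the transfer-learning configuration of the study: frozen backbone,
trainable sigmoid head, head learning rate 0.01. Training is plain gradient
descent (`w <- w - eta * g`), matching the printed local update rule; no
momentum is stated in the study and none is added. Only frozen-backbone
training is implemented — it is the configuration the study ran, and it
lets per-sample features be computed once and cached across rounds. The
loss is mean binary cross-entropy on the sigmoid output.

## Federation

One communication round distributes identical global weights to all K
centers, runs exactly 7 local gradient iterations per center (batch sizes
chosen as a near-equal partition, `ceiling(n/7)` or one less, so every
center traverses its data in the same number of iterations; centers smaller
than 7 samples recycle), and aggregates:

* **FL** (FederatedAveraging): coefficients `n_k / n`, proportional to
  center sample size (subject-timepoints; subjects would give identical
  coefficients since every subject contributes exactly two samples);
* **FL-EV** (equal voting): coefficients `1/K`;
* **CDS** (pooled baseline): a single model trained for one epoch over the
  pooled stream with `7K` batches, so one CDS epoch costs the same number
  of gradient steps as one federated round.

With one center and identical batching, FL and CDS produce bit-identical
trajectories — a degenerate-equivalence check the tests exploit. Early
stopping monitors the negative `n_k`-weighted mean of per-center validation
cross-entropy (each center evaluates locally; weighting mirrors FedAvg; the
study states only that validation performance is monitored, without
naming the metric — loss is robust to single-class validation sets at
small centers, AUC is not), with patience 10 by default and restoration of
the best round's weights.

## Evaluation

Two split geometries over *subjects* (ED/ES co-assignment is therefore
structural):

* **CCV**: every center contributes a label-stratified ~20% of its
  subjects to each of 5 test folds (largest-remainder rounding with a
  randomized starting fold); the remaining 80% split 90/10 per center into
  training/validation.
* **LCO**: one fold per center; the fold's test set is that center in its
  entirety, and the harmonization reference for the fold excludes it.

AUC is computed from midranks (ties count 1/2). Per-seed total AUC pools
the test predictions of all folds — pooling and per-center averaging give
different answers, and the tests pin the pooled convention; per-center AUC
pools that center's test predictions across folds. Tables report mean and
*population* standard deviation over the repeated seeds (default `0:4`;
the study does not state which std convention its tables use).

## Problem sizes and what the tests show

The test and acceptance suites run the full pipeline at reduced scale —
two to three centers, 6 to 20 subjects per center, 15 communication
rounds, 3 seeds, `small3d` — sizes at which the whole suite completes on
one CPU in minutes while still exercising every contract at full fidelity
(the 150x150x10 window, 7-iteration rounds, and all three frameworks are
never scaled down). At these sizes the easy cohort is recovered to pooled
CCV AUC at or near 1.0 by CDS, FL and FL-EV alike, and removing
harmonization under strong center shift lowers leave-center-out AUC
relative to CCV — the directional analogue of the out-of-site performance
gap the full-scale study reports. The published full-scale AUC tables
themselves require the registration-gated imaging cohorts, pretrained
video weights and accelerator-scale training, and are out of scope here.

## Known limitations

* The phantom's two-parameter geometry cannot produce borderline cases;
  sensitivity analyses near the 15 mm threshold need a narrowed separation
  via `geometry_config()`.
* Backbone fine-tuning (non-zero backbone learning rates) is not
  implemented; the backbone is a fixed feature extractor.
* `resnet3d_18` forward passes in plain R are impractical for training;
  the architecture exists for construction-level fidelity (parameter
  counts, weight exchange formats) and interface parity with `small3d`.
* Communication costs, client dropout, secure aggregation and differential
  privacy are out of scope; privacy preservation here means the interface
  discipline that only weights and histogram aggregates cross center
  boundaries.
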