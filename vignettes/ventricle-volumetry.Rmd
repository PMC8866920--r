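---
title: "Thickness-agnostic ventricle segmentation and volumetry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thickness-agnostic ventricle segmentation and volumetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ventricular enlargement is the imaging hallmark of normal pressure
hydrocephalus (NPH) and related disorders. The quantities clinicians
want are the ventricular volume (VV, the summed volume of the right
lateral, left lateral, third and fourth ventricle), the intracranial
volume (ICV), and the relative ventricular volume VV/ICV, which
normalizes away head-size differences. Manual delineation takes tens
of minutes per scan; `ventseg` implements an automatic pipeline:
slice-wise multi-class segmentation of CT or MRI head volumes,
followed by exact voxel-counting volumetry and the agreement
statistics used to validate automatic against manual measurements.

A practical obstacle is slice thickness. Clinically archived scans are
often thick-slice (roughly 5-8 mm between slices) while research-grade
thin-slice scans are rare and expensive to annotate. The two regimes
have visibly different statistics (thick slices are through-plane
averages), so a model trained on one degrades on the other. The
package's training protocol addresses this with two stages:

1. **Supervised pretraining** on labeled thick slices with per-pixel
   cross-entropy
   $L_S = -\tfrac{1}{HW}\sum_n \sum_c y^{n,c}\log p^{n,c}$.
2. **Joint training** in which every optimization step draws one
   labeled thick batch and one *unlabeled* thin batch and minimizes
   $L = L_S + \lambda\,L_T$, where the entropy loss
   $L_T = -\tfrac{1}{C}\sum_c f(C\,p_c)$ with $f(x) = x^2 - 1$
   (averaged over pixels) is zero for a uniform prediction and
   $-(C-1)$ for a one-hot one. Minimizing $L_T$ pushes thin-slice
   predictions toward confident decisions while $L_S$ anchors the
   decision boundaries, shrinking the thick/thin domain gap without
   thin-slice labels.

$\lambda$ defaults to 1 (the plain sum); it is config-exposed for
ablations. Whether the entropy term should also touch thick-slice
predictions is ambiguous; the default applies it to thin slices only,
with `entropy_on_thick = TRUE` available.

# The segmenter

The network is a slice-wise encoder-decoder operating on
$H \times W \times 3$ inputs (grayscale slices replicated to three
channels, the input format of natural-image encoders):

* **Encoder**: a three-stage residual convolutional encoder (stride-2
  stem, two further stride-2 downsamplings, one residual block per
  stage). Every convolution is followed by instance normalization --
  the batch-size-agnostic, evaluation-deterministic counterpart of the
  batch normalization found in standard residual encoders -- and ReLU.
* **Decoder**: three sub-pixel-convolution stages. Each stage
  convolves to $C \cdot r^2$ channels and applies the sub-pixel
  rearrangement $SP(\cdot)$, which maps an
  $H \times W \times C r^2$ tensor to $rH \times rW \times C$ by
  writing each $r^2$-channel block into an $r \times r$ spatial patch
  (row-major). The first two decoder stages add skip connections from
  the matching encoder stage. With upscale factors $(2, 2, 2)$ the
  decoder exactly restores the input resolution.
* **Head**: a 1x1 convolution and per-pixel softmax; ties in the
  argmax break toward the lowest class index, so an exactly uniform
  prediction yields background.

Two design extensions beyond the minimal encoder/sub-pixel-decoder
description deserve explicit mention, because the bare architecture is
not trainable to useful quality at desk scale:

* **Skip connections** from encoder to decoder stages restore spatial
  detail lost to the stride-8 bottleneck.
* **Coordinate channels**: two fixed channels holding the normalized
  $(y, x)$ position are appended to each decoder stage's input. The
  four ventricle classes are defined by *where* a CSF structure sits
  (right or left of the midline, inferior fourth ventricle); a fully
  convolutional network's only other access to absolute position is
  the weak zero-padding boundary effect. The coordinate channels carry
  no gradient and add 18 weights per decoder stage.

Initialization is He-normal, with the instance-norm gain of each
residual block's second convolution starting at zero (each block
begins as the identity) and the head's weights scaled by 0.05 so
training starts from near-uniform probabilities. Without these the
13-convolution stack starts saturated and optimizes poorly.

The whole-brain model used for ICV is the same architecture with
`n_classes = 2`; both models share every code path.

# Preprocessing

Per volume: intensities are clipped to the empirical 2.5%/97.5%
quantiles and then z-scored to mean 0, SD 1 (population SD). Clipping
before normalization is the default order (`preprocess_volume(order =
"normalize_clip")` gives the alternative, which clips on z-scores).
Quantiles use the inverse-ECDF convention (type 1), which makes
clipping exactly idempotent. Training augmentations are a horizontal
flip (image and mask flipped by the same draw) and photometric scaling
of hue/saturation/brightness by factors drawn from [0.8, 1.2]; with
three identical channels the hue and saturation factors are no-ops and
the step reduces to a brightness scale. The evaluation path is fully
deterministic.

One augmentation caveat found the hard way: horizontal flips are
**off** in the fitting function's default. Classes 1 and 2 are
lateralized (right/left lateral ventricle), and a flip that mirrors
the image while keeping class identities makes the two classes
statistically indistinguishable -- the model then provably cannot beat
chance on them. Masks are never relabeled under augmentation (the
augment contract forbids new labels), so the safe default is no flip;
brightness scaling stays on.

# Training schedule

Defaults follow the full-scale protocol: SGD (momentum 0.9, the
momentum value being unstated in descriptions of this protocol and
fixed here by convention), 200 supervised epochs at learning rate 1e-3
with linear decay to ~0, then 100 joint epochs at 1e-4, weight decay
1e-5 throughout (applied to convolution kernels only, never to biases
or normalization parameters). The split into training and held-out
cases is at the case (subject) level, never the slice level, with 20%
held out.

The **desk preset** (`desk_config()`) is what the test suite and
acceptance script exercise on one CPU: 64 x 64 slices, encoder widths
(8, 16, 32), 20 training phantom cases, 60 supervised epochs at
stage-1 learning rate 0.25 with batch size 4, then 6 joint epochs at
stage-2 learning rate 3e-5. The stage-1 rate is far above the
full-scale default because the desk network is roughly three orders of
magnitude smaller and instance-normalized throughout; the class
imbalance (ventricles are ~2% of pixels) plus the four-way class
symmetry produce a long plateau before the decision boundary forms,
and at 1e-3 the desk model does not leave that plateau within any
reasonable epoch budget. The stage-2 rate sits well below the
full-scale 1e-4: entropy minimization sharpens whatever the model
currently predicts, so a hot joint stage actively erodes
minority-class regions (confidently-background pixels pull uncertain
neighbors over the decision boundary), while at 3e-5 the entropy loss
still falls with no measurable Dice cost. In stage 2, thick and thin gradients are summed into a
single update by default (`update_mode = "alternating"` performs
consecutive per-stream updates instead).

# The phantom generator

No clinical data ship with the package, so every stage is tested on
synthetic head phantoms with analytically known geometry: an
ellipsoidal intracranial compartment, four disjoint ellipsoidal
ventricles (enlarged to NPH-like proportions, VV/ICV ~ 8%), a bright
skull shell for CT, and per-compartment Gaussian intensities (CT-like:
air at -1000, CSF-dark ventricles near 6, parenchyma near 35, skull
near 700, in Hounsfield-flavored arbitrary units; an MRI T1-like
preset swaps the contrast). A voxel belongs to a compartment iff its
center lies inside the ellipsoid; ground-truth volumes are recorded by
exact voxel counting, so the volumetry module's output on the true
labels reproduces them identically by construction.

Thick-slice scans are emulated by `degrade_thickness()`: groups of `k`
thin slices are averaged into one thick slice (labels take the group's
central slice, the nearest-neighbor convention for masks), and the
slice spacing multiplies by `k`. The desk conditions use thin spacing
(2.4, 2.4, 2.0) mm with `k = 4`, i.e. 8 mm thick slices -- the
clinically realistic thick regime. Volumes are classed as "thick" at
or above a configurable 3 mm slice-spacing threshold; the boundary is
a package convention, since thick-slice acquisitions run ~5-8 mm and
thin ones <= ~1-3 mm.

The default grid is a 64 x 64 x 20 slab covering 40 mm about the
ventricle plane rather than the whole head. This is deliberate: near
the brain apex, a thickness-averaged slice contains a central dark
partial-volume blob that is *pixel-for-pixel indistinguishable* in 2-D
from a ventricle-bearing mid-slice, while carrying the opposite label.
A slice-wise segmenter (which never sees its z position) cannot
resolve that ambiguity, and no amount of training fixes it; real heads
are less pathological because apex anatomy does not mimic mid-slice
anatomy. Restricting the phantom to the ventricle-bearing slab keeps
the desk-scale task honest about what a 2-D model can represent.
Cohorts jitter each ventricle's semi-axes (+-15%) and center (+-3 mm)
and the head size (+-7.5%), so per-case VV and ICV vary as they would
across subjects.

What the phantoms do **not** emulate: cortical folding, partial-volume
fractions at in-plane boundaries, scanner noise spectra and artifacts,
CT Hounsfield calibration, or any intensity statistics of specific
devices. Passing the desk-scale suite therefore demonstrates that the
pipeline's machinery (losses, optimization, volumetry, statistics) is
correct and that the two-stage protocol behaves as designed on data
with a known answer -- not that the desk-sized network would segment
clinical scans.

# Volumetry and agreement statistics

Volumes are exact voxel counts times the voxel volume
$r_x r_y r_z$ (mm^3, reported in ml), with the spacing read from the
NIfTI header, never assumed. VV/ICV is the exact ratio in percent; an
ICV of zero is an error, never a silent NaN. Ventricle voxels
predicted outside the predicted brain mask (the two models are
independent) are counted and flagged with a warning.

Agreement between paired manual and automatic measurements is
summarized by:

* **Dice similarity coefficient**, per class and pooled over the union
  of the four ventricle classes; the pooled value is the single "VV
  DSC" figure (the pooling rule is a package convention). Two empty
  masks have DSC 1 (perfect agreement on absence); a class absent from
  both maps is reported NA and excluded from means.
* **ICC(2,1)** -- two-way random-effects, absolute-agreement,
  single-measure, from the standard mean-squares decomposition. The
  variant is fixed here by convention; unlike Pearson's r it penalizes
  constant offsets.
* **Pearson correlation** with a two-sided p-value.
* **Bland-Altman analysis**: differences are manual minus auto (the
  direction is inferred from the convention that a positive bias means
  the automatic method under-measures), bias = mean difference, limits
  of agreement = bias +- 1.96 SD.

# Numerical choices and degenerate inputs

* Cross-entropy clamps log arguments at 1e-12 (warning, no
  infinities); a zero-variance volume z-scores to zeros with a warning.
* Instance norm uses epsilon 1e-5 inside the square root.
* Bicubic resampling uses the Catmull-Rom kernel (a = -0.5) with
  clamped borders and row renormalization; masks resize by nearest
  neighbor and can only lose, never gain, labels.
* Sub-pixel rearrangement is validated as an exact bijection (its
  inverse is also exported); non-divisible channel counts are errors
  naming C and r.
* All randomness (phantom intensities, cohort jitter, weight
  initialization, batch order, augmentation) derives from explicit
  seeds through R's RNG; fits with equal seeds are bit-identical, and
  the simulate-train-measure-evaluate pipeline is byte-reproducible.
* Degenerate geometry (a ventricle ellipsoid leaving the brain,
  overlapping classes, non-positive spacing) is rejected at
  construction with a diagnostic naming the offending voxel.

# Problem sizes used by the tests

The acceptance suite trains the desk preset on a 20-case cohort (16
train / 4 held out) for three fixed seeds, checks held-out pooled
ventricle Dice and the stage-2 non-degradation bound, and reruns the
full pipeline twice on a 6-case cohort to verify byte-identical
reports. Volumetry is verified against a naive triple-loop counting
oracle on 100 random label maps and against analytic ellipsoid volumes
at 1 mm spacing. These sizes are the package's chosen desk-scale study
conditions; the full-scale schedule remains available in
`train_config()` for users with real cohorts and more compute.

# Known limitations

* The segmenter is strictly 2-D slice-wise; structures whose identity
  depends on z position are outside its representational power (see
  the slab rationale above).
* Per-class discrimination among the four ventricle classes at desk
  scale is weaker than foreground/background separation; the pooled
  (union) segmentation drives VV and is what the acceptance criteria
  check. Per-class Dice values are reported, not guaranteed.
* ImageNet-pretrained encoder weights are supported as an optional
  flag in the configuration but none ship with the package; the
  default is random initialization.
* DICOM ingestion, bias-field correction, registration and
  surface-based volumetry are out of scope; NIfTI-1 is the sole
  clinical format.
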