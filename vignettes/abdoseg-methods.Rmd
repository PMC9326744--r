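---
title: "Multi-organ abdominal MRI segmentation and volumetry: methods and design"
author: "abdoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-organ abdominal MRI segmentation and volumetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

In autosomal dominant polycystic kidney disease (ADPKD) the kidneys — and
often the liver and spleen — are progressively enlarged by fluid-filled
cysts. Total kidney volume indexed to height (ht-TKV, mL/m) is the accepted
prognostic biomarker, and it is measured by contouring organ outlines on
every slice of an axial T2-weighted abdominal MRI. Manual contouring is slow
and observer-dependent; `abdoseg` implements a model-assisted workflow in
which per-organ neural networks propose contours that an expert would then
correct.

The package covers the full measurement chain: reading DICOM series or NIfTI
volumes, per-slice preprocessing, training per-organ binary 2D segmentation
networks, combining their outputs into a single multi-organ label map,
volumetry, and the agreement statistics used to evaluate such a pipeline
(Dice similarity, Lin's concordance, RMSE, percent error, Bland–Altman
limits, interobserver SD and ICC). Because patient MRIs cannot ship with a
package, a synthetic abdominal phantom generator stands in for them, making
every stage trainable and testable end to end.

## The segmentation model

Each organ class — kidney (both kidneys as one class), spleen, liver — is
segmented independently by its own binary 2D network. The architecture is a
U-shaped fully convolutional encoder–decoder: five encoder stages
(3×3 convolution, ReLU, 2×2 max-pooling), a bottleneck convolution, and a
decoder of exactly five nearest-neighbour upsampling stages, each followed
by a skip concatenation with the matching encoder resolution and a 3×3
convolution, closing with a 1×1 convolution and a sigmoid. Two presets share
this topology: `"default"` (512×512 input) and `"tiny"` (64×64 input), the
latter sized so the whole training loop runs in minutes on one CPU. No
deep-learning framework is available in this dependency set, so the forward
and backward passes are implemented in the package itself (im2col + GEMM
convolutions in compiled code, hand-derived backpropagation, verified
against finite differences in the test suite).

Training minimises a combined loss

$$L = w_d\left(1 - \frac{2\sum_i p_i g_i + \varepsilon}{\sum_i p_i + \sum_i g_i + \varepsilon}\right) + w_{ce}\,\mathrm{mean}_i\left[-g_i \log p_i - (1-g_i)\log(1-p_i)\right]$$

with equal weights $w_d = w_{ce} = 1$ and smoothing $\varepsilon = 1$ in
both numerator and denominator, which keeps the Dice term finite on empty
masks. With binary predictions and $\varepsilon \to 0$ the Dice term equals
$1 - \mathrm{DSC}$, a cross-module identity the tests assert. The optimizer
is rectified Adam wrapped in Lookahead (sync period 5, interpolation 0.5),
batch size 8. After every epoch the pooled validation Dice at threshold 0.5
is computed and the best-scoring parameters are retained; training stops at
the epoch budget or after a configurable patience without improvement —
an automatable stand-in for convergence judged by eye on monitoring curves.

Subjects are assigned to train/validation partitions by stratified sampling
over TKV quartile × pulse-sequence strata, with all scans of a subject
co-assigned so no subject leaks across partitions.

## Preprocessing: asymmetric train and inference paths

Every slice is min–max normalized (minimum → 0.0, maximum → 1.0). A constant
slice maps to all zeros: this avoids a divide-by-zero and marks the slice as
carrying no contrast.

The spatial paths differ deliberately. Training maps each slice to 640×640
and center-crops to 512×512, concentrating capacity on central anatomy.
At inference the crop is removed: slices are resized directly to the model
input with no cropping, because organs near the image border — typically a
massively enlarged liver — would otherwise be truncated, producing
artifactual straight label edges. Probabilities are resized back to the
native grid afterwards.

Two choices here were genuinely open:

* **Aspect handling of the 640 mapping.** Implemented as an
  aspect-preserving resize of the longer side to 640 with zero-padding of
  the shorter side. Stretching was the alternative; padding avoids
  anisotropic distortion of organ shape and makes the label geometry exact
  under the paired nearest-neighbour path.
* **Interpolation.** Bilinear for intensities and probabilities, nearest
  neighbour for labels — labels must stay categorical.

Augmentation (off by default in training configs; the suite is exercised by
its own tests) is a minimal standard set: rotation ≤ 10°, isotropic scale
± 10%, translation ≤ 5%, horizontal flip, brightness/contrast jitter —
applied with the identical spatial transform to image and label.

## Conflict adjudication and the midline split

Each network claims voxels where its probability strictly exceeds 0.5
(a voxel at exactly 0.5 is background: "above the threshold" reads as a
strict inequality, and the strict rule makes thresholding deterministic). Voxels claimed by more than one organ are adjudicated by a
single ordered scan with fixed priority **kidney > spleen > liver**:
kidney/liver overlaps default to the kidney (border cysts are far more often
renal), spleen/liver overlaps to the spleen. The scan is total, so every
claimed voxel receives exactly one label and adjudication is idempotent.

A legacy diagnostic encoding is retained for audit: overlap voxels get the
sum of the claiming indices (right kidney 1 + liver 4 = 5, rendered pink in
ITK-SNAP). The encoding is ambiguous — left kidney 2 + spleen 3 also sums to
5 — which is exactly why it was superseded by priority adjudication;
`sumOverlapAudit()` tabulates and flags these collisions.

Because the kidneys are segmented as one class, right/left identity is
restored geometrically: kidney voxels on the patient-left of the volume's
mid-sagittal plane become left kidney (label 2), all others right kidney
(label 1). Voxels exactly on the plane go right — an arbitrary but
deterministic tie rule on odd-width grids. The plane is a property of the
volume grid, not an anatomical landmark, and it is applied per volume, not
per slice; a kidney that genuinely crosses the midline will be split
geometrically, a known and accepted failure mode of this class of rule.
All volumes are reoriented at read into a canonical patient frame (axis 1
right→left, axis 2 anterior→posterior, axis 3 inferior→superior), so the
midline is always a constant-index plane.

## Volumetry and agreement statistics

Organ volume is voxel count × voxel volume (mm³) / 1000; TKV = right +
left kidney exactly; ht-TKV = TKV / height. The agreement suite implements:

* **DSC** $= 2|A \cap B| / (|A| + |B|)$. Two empty masks return 1.0: if
  both observers found nothing, they agree perfectly. (The alternative, 0,
  would penalize correctly absent organs.)
* **Lin's concordance** $2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$
  with population (1/n) moments; undefined (error) when both series are
  constant.
* **RMSE** and **mean percent error**. Percent error is computed as the
  mean of per-case absolute errors $|y_i - x_i|/x_i$: per-organ percent
  errors are conventionally reported as positive magnitudes, and a signed
  mean would let over- and under-segmentation cancel. This is an
  interpretation; the signed
  per-case differences remain available through the Bland–Altman payload.
* **Zero-error count** after rounding to the nearest 1 mL, matching
  whole-mL volume reporting.
* **Bland–Altman** on the percent scale: differences signed as
  (prediction − truth) over the pair mean, bias ± 1.96 SD limits.
* **Interobserver SD**: per-case sample SD across observers, averaged over
  cases.
* **ICC(2,1)** — two-way random-effects, absolute agreement, single rater —
  computed from the variance decomposition. The variant is not dictated by
  the problem statement; absolute agreement between exchangeable observers
  is the quantity a reproducibility table compares, which is ICC(2,1).
  The estimator is cross-checked in the tests against an `aov()`
  mean-squares oracle and recovers a simulated intraclass correlation within
  ±0.05 at n = 200 cases.

## The phantom generator: what it does and does not emulate

`phantomSpec()` / `generatePhantom()` render four non-overlapping organ
ellipsoids (right kidney, left kidney, spleen, liver) at realistic relative
positions and sizes on an anisotropic lattice (default 64×64×24 voxels at
6×6×9 mm, a 384 mm field of view). Voxel membership is decided by
center-point containment, which makes a brute-force lattice scan an exact
volume oracle — the tests use exactly that. Intensities follow T2 contrast:
liver darkest (0.25), kidney parenchyma 0.45, spleen 0.65, fluid-filled
cysts brightest (1.0) on a 0.08 background, plus additive Gaussian noise
(SD 0.02 by default). Cysts are spheres drawn fully inside their parent
organ; they brighten the image but belong to the organ in the truth — as a
radiologist would label them. Default kidney semi-axes give a TKV near
870 mL (ht-TKV ≈ 510 mL/m at 1.7 m), i.e. clearly cystic kidneys;
per-subject jitter (global kidney scale SD 0.15, per-axis shape SD 0.06,
position SD 5 mm) spreads cohort TKV widely enough to occupy the quartile
strata. Cyst burden is a free parameter: no quantitative cyst-count
distribution per disease stage was available to calibrate it.

`simulateObserver()` emulates interobserver contouring variability the way
observers work — contour by contour: per organ and per axial slice a signed
boundary offset ~ N(0, scale) is applied as whole-voxel 2D dilation/erosion
layers, the fractional remainder as one further layer with matching
probability. Zero scale returns the truth exactly; volume SD across
simulated observers grows monotonically with the scale, which is what the
interobserver machinery needs to be exercised meaningfully.

What the phantom deliberately does **not** model: MRI physics (coil shading,
fat saturation, sequence-dependent contrast), anatomical shape beyond
ellipsoids, and the confounders that cause real false positives (fluid-filled
stomach, gallbladder). Passing phantom tests therefore demonstrates that the
pipeline's machinery — training dynamics, adjudication, split, volumetry,
statistics — is correct, not that the shipped tiny networks would segment
patient MRIs; clinical-scale accuracy claims require patient data this
package does not contain.

## Problem sizes and numerical choices

The self-check (`endToEndPhantomCheck()`) and the corresponding test train
the three tiny networks on a 12-subject noise-free cohort (70/30 split:
8 training subjects, 64×64 slices) for at most 30 epochs with learning rate
3e-3, then require held-out Dice ≥ 0.8 for all four labels after the
midline split — sizes chosen so the whole loop is a minutes-scale CPU run
while still exercising every stage. Other numerical choices: He-normal
initialization; Dice smoothing ε = 1 during training and ε → 0 only in
identity checks; probabilities clamped to [1e-7, 1 − 1e-7] inside the
cross-entropy; strict `>` at the 0.5 threshold; slice-gap non-uniformity
tolerated to 1% before the reader warns and falls back to the median gap.

## Known limitations

* 2D slice-wise inference stacked into 3D; no 3D context or smoothing, and
  no connected-component cleanup of false positives.
* The mid-sagittal split misassigns kidney tissue that crosses the midline.
* The DICOM reader supports single-frame, uncompressed, explicit-VR
  little-endian, axis-aligned series only.
* Multi-class (softmax) single-model training is out of scope by design:
  per-organ binary networks with explicit adjudication are the method here.
* Phantom realism is deliberately minimal (see above); generator defaults
  are study conditions, not tuning knobs.
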