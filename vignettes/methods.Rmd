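---
title: "Methods: simulated risk-class segmentation and calibration for self-steering tomosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated risk-class segmentation and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(steersim)
```

## The question the pipeline answers

Digital breast tomosynthesis (DBT) acquires a handful of low-dose
projections along a fixed scanning arc. A next-generation system with
multidirectional source motion could instead *steer* the remainder of its
scan around suspicious areas — if those areas can be found in the very
first low-dose projection (the scout image). `steersim` implements an in
silico feasibility study of exactly that: can a single simulated low-dose
projection of a breast phantom be segmented into risk classes
(background/skin, predominantly adipose, predominantly dense, lesion)
reliably enough to localize suspicious findings, and how much does post
hoc probability calibration help?

The pipeline has six stages, each a package module:

1. **Phantom cohort** — compressed-breast voxel phantoms with fractal-noise
   parenchyma and embedded lesions.
2. **Projection simulation** — Siddon ray tracing of the central low-dose
   projection with automatic-exposure-control (AEC) scaling and Poisson
   noise.
3. **Ground truth** — label maximum intensity projections (MIPs) folded
   into four risk classes, rescaled and aligned to the projection grid.
4. **Segmentation** — a small convolutional encoder-decoder trained with
   weighted cross-entropy.
5. **Dirichlet calibration** — post hoc adjustment of the predicted class
   probabilities, `softmax(W ln q + b)`.
6. **Evaluation** — pooled ROC/AUC, Dice/Jaccard, classwise expected
   calibration error, and finding-level FROC analysis, before and after
   calibration.

## Phantom model

**Outline.** Patient-derived statistical outline models are not
reproducible from public sources, so the outline is parametric: a
super-ellipse (exponent 2.5) in the axial plane spanning the chest wall to
the chest-wall-to-nipple distance (CND), extruded between two flat
compression surfaces separated by the compressed breast thickness (CBT),
with a closed skin shell (default 1.5 mm, a typical mammographic skin
thickness). This preserves everything downstream stages consume — CBT,
CND, interior and skin masks — without claiming anatomic shape statistics.
Cohorts draw CBT from 30–70 mm and CND from 50–110 mm, the compressed
ranges the study design targets.

**Parenchyma.** Interior voxels are textured with octave-summed
gradient-lattice (Perlin) noise and thresholded at a quantile: voxels
above the `1 - vbd` quantile become dense, the rest adipose, so the
realized volumetric breast density (VBD) equals the target up to quantile
granularity (the package tests assert ±1% on million-voxel interiors).
Low octaves provide coarse tissue compartments, high octaves fine
texture, so no separate coarse-tissue partitioning step is needed.
Defaults — 6 octaves, base frequency 1/40 mm⁻¹, persistence 0.5,
lacunarity 2.0 — place the coarsest structure at breast scale (~40 mm)
and are exposed in `perlin_config()`; they are package defaults, not
values validated against patient texture statistics.

**Lesions.** Four size models span the reported soft-tissue finding
range: model I is a 7×7×7 mm ellipsoid with density weight `w = 0.20`;
models II–IV are spiculated with nominal boxes 9×8×3, 10×14×4 and
15×15×4 mm and `w = 0.35`. Spicule geometry is not published, so the
package builds an ellipsoidal core at 60% of the nominal semi-axes plus
seeded radial spicules (the six axis directions plus 2–10 random ones)
tapering to the nominal bounding ellipsoid; this keeps the mask's
bounding box at the nominal dimensions (within one voxel) and guarantees
a single connected component, with each spicule's center line rasterized
so connectivity survives coarse voxel pitches. Insertion is voxel-
additive: covered interior voxels are relabelled lesion and remember
their pre-insertion label; two lesions per phantom are placed at random
left-right/posteroanterior positions, always centered craniocaudally,
rejecting placements that touch skin/background or overlap (minimum
center separation: sum of bounding-sphere radii).

**Splits.** Cohort records are stratified by VBD tercile × lesion shape
pair × CBT tercile and apportioned to train/validation/calibration/test
by controlled rounding: largest remainder within each stratum, then
single-record swaps between strata until the global quotas are exact —
so every stratum stays within one record of proportionality and the
global sizes match the configured ratio exactly (168/24/24/48 at the
full 264-phantom scale; 16/4/4/8 at demo scale).

## Projection model

The acquisition geometry is the prototype system's: source-image
distance 738.01 mm, stationary 239.36 × 304.64 mm detector with
0.085 × 0.085 mm elements, central projection with the source on the
normal through the chest-wall edge midpoint. A `scale` parameter
coarsens the detector element (keeping the physical extent) so
desk-scale studies stay tractable; the demo uses 0.68 mm elements.

Attenuation is monoenergetic at a 20 keV effective energy with
ICRU-44-style soft-tissue coefficients (adipose 0.047, skin 0.075,
dense/glandular 0.0802 mm⁻¹); air is treated as non-attenuating so
unobstructed pixels read exactly the unattenuated fluence. Polyenergetic
W/Al spectra, scatter and detector blur are out of scope — the
segmentation task consumes relative contrast, not absolute dosimetry.
Lesion voxels attenuate as `(1 − w)·μ_underlying + w·μ_dense`,
operationalizing "adding a proportion w of dense tissue per voxel".

Line integrals use an exact Siddon/Amanatides–Woo traversal (compiled;
tested against a fine uniform-sampling oracle at 2% and against
Beer–Lambert closed forms at 1e-6). Exposure follows an AEC-like rule
`photons = target · exp(μ_eff(vbd)·cbt)` with `μ_eff` the
adipose/dense mixture at the phantom's VBD, so the transmitted count
behind the breast stays near the configured low-dose target (50
photons/pixel by default) across thicknesses and densities. Quantum
noise is Poisson with a per-image seed; the detector is an ideal photon
counter.

## Ground truth

The five voxel labels are ordered background < skin < adipose < dense <
lesion, so an orthographic maximum along the craniocaudal axis returns
the highest-risk tissue crossed by each column; folding background and
skin together yields the four risk classes. The MIP is computed on the
phantom grid and rescaled to the detector grid by nearest neighbor
through the central-projection magnification of the phantom mid-plane
(CBT/2 above the support) — the mid-plane choice minimizes worst-case
parallax misalignment, and nearest neighbor guarantees no interpolation-
created classes. Image/label pairs are then cropped to the largest
magnified posteroanterior extent over the cohort (removing background
rows on the nipple side) and downsampled — images by block averaging
(preserving radiometry), labels by nearest neighbor (preserving
integrality) — to the training dims (360 × 600 at full scale, 96 × 64 in
the demo).

## Segmenter

A U-Net-style 2D encoder-decoder: two 3×3 convolution + ReLU blocks per
level, 2×2 max pooling, nearest-neighbor upsampling with skip
concatenation, 1×1 softmax head over the four classes. The network,
its backpropagation and the Adam optimizer are implemented in the
package (convolutions via compiled im2col/col2im); the backward pass is
verified against numeric gradients in the tests. Inputs are
log-transformed and standardized per image. The loss is weighted
cross-entropy with class weights defaulting to inverse pixel frequency
normalized to mean 1 — lesion pixels are on the order of 1% of the
image, and unweighted training collapses to the majority classes. Early
stopping monitors validation loss (patience 6 at demo scale, 20 at full
scale); learning rate 3e-4 with Adam matches the study design, as does
the 250-epoch cap at full scale. The demo configuration (depth 3, 8 base
channels, batch 4, 20-epoch cap) is sized for single-CPU runtimes of a
few minutes per study; it is *not* claimed to match the original
GPU-scale U-Net capacity, and the paper-scale configuration is provided
behind an explicit compute warning. A per-pixel multinomial-logistic
baseline (`fit_pixel_baseline()`) ships for fast deterministic exercise
of the downstream stages.

## Dirichlet calibration

Small networks trained on imbalanced pixel data are overconfident,
especially for the rare lesion class. Dirichlet calibration maps each
predicted probability vector q through `softmax(W ln q + b)` (a k×k
matrix and k-vector, identity-initialized). The fit minimizes the mean
multinomial negative log-likelihood of the true classes on the held-out
calibration split by BFGS with the analytic gradient; pixels are treated
as independent instances (a stated simplification — neighboring pixels
are correlated in reality), and large splits are subsampled to 2×10⁵
pixels stratified by class. The fitted map never increases the
calibration-split NLL relative to identity (the identity is returned if
optimization fails to improve it). Probabilities are clamped at 1e-12
before logarithms. No ODIR-style regularization is applied by default.
(W, b) are identifiable only up to per-row shifts, so parameter-recovery
tests compare in probability space.

Calibration quality is summarized by the classwise expected calibration
error: probabilities for each class are binned into m = 10 equal-width
bins (last bin right-closed), and the bin-size-weighted absolute gaps
between mean predicted probability and observed positive fraction are
averaged over bins and classes. As printed in the source formula the
class index runs 0..k with a 1/k prefactor — an off-by-one; the package
implements the mean over the k = 4 classes. All four classes, including
background/skin, enter by default.

## Evaluation

*Segmentation*: one-vs-rest ROC curves over pooled test pixels (AUC by
trapezoid; operating point minimizing the distance to the ideal corner,
reporting TPR/TNR/PPV/NPV), and pooled per-class Dice and Jaccard from
the argmax class maps (ties toward the lower class code — the "safer"
call). Pooling (rather than per-image averaging) is used for both,
matching the pooled-ROC convention.

*Detection*: suspicious findings are 8-connected components of
lesion-class pixels (8-connectivity avoids splitting thin spiculations).
A truth cluster is a TP when any predicted lesion pixel overlaps it,
else an FN; a predicted component with no truth overlap is one FP; a
predicted component bridging several truth clusters yields a TP per
cluster and no FP, so TP + FN always equals the number of truth
clusters. FROC curves sweep the class-3 probability threshold from 1.00
to 0.00 in 0.01 steps; sensitivities at 2 and 5 FP/image are read off by
linear interpolation. The headline TP/FP/FN counts are computed from the
*output predictions* (argmax class maps), the study's own detection
readout; counts at the class-3 ROC operating threshold are also reported.
The two can diverge after calibration: calibrated class-3 probabilities
are compressed toward zero, so the pooled-ROC operating threshold drops
sharply and noise speckle fragments into many small components even as
pixel-level specificity improves — a scale artifact of thresholding, not
of the predictions themselves, and the reason the operating-threshold
counts are reported but not used as the primary detection metric.

## What the demo study shows (and does not)

The demo configuration — 32 phantoms split 16/4/4/8, 0.68 mm detector
elements, 96 × 64 training pairs, the tiny segmenter — runs end to end
in about three minutes on one CPU and reproduces the *directional*
findings: Dirichlet calibration reduces the calibration-split NLL, and
on the test split reduces the classwise-ECE and the number of FP
findings from the predicted class maps (with the accompanying increase
in FN findings). Absolute metric levels (per-class AUC ≈ 0.80–0.94,
lesion Dice far below the full-scale study's values) are not comparable
to a GPU-trained U-Net on 264 phantoms at 360 × 600 resolution and are
not asserted anywhere in the tests.

The synthetic cohort emulates compressed-breast geometry, multi-scale
parenchymal texture, density-controlled lesion contrast and quantum
noise. It does not emulate ductal/vascular anatomy, scatter, detector
blur or lag, polyenergetic beam hardening, or reader-validated realism —
so green tests demonstrate the pipeline's internal correctness and the
calibration effect under the stated model, not clinical performance.

## Numerical choices

- Probability clamping at 1e-12 before every logarithm.
- Argmax ties break toward the lower class code (deterministic).
- Reliability bins: equal width, last bin right-closed, empty bins
  contribute zero.
- BFGS convergence: relative tolerance 1e-10, 200 iterations cap;
  identity fallback keeps the NLL contract.
- All randomness derives from a single master seed through a
  multiplicative hash (`derive_seed`), kept below 2³¹; regenerating any
  phantom from its manifest record is bit-identical.
- Degenerate inputs: classes absent from a calibration split are label-
  smoothed (warning); ROC/FROC on splits lacking the class raise typed
  errors rather than returning NaN.
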