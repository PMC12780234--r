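---
title: "Models and methods behind pelvamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pelvamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvamp)
```

## Scope

pelvamp implements the computational core of an MRI reading-support pipeline
for deep endometriosis: measuring fibrotic plaque depth on the posterior
uterine surface, sizing ovarian endometriotic cysts (OECs), predicting
inter-organ pelvic adhesions from organ-shape radiomics, and the evaluation
statistics such pipelines are judged by. No patient data ships with the
package; every quantitative claim is demonstrated on synthetic pelvic
phantoms whose ground truth is analytic. This vignette documents the models,
their parameters, and the design decisions that were genuinely open.

## The phantom model

A phantom is a pair of 3D volumes (a sagittal-convention "T2" volume for
organs and plaque, an axial-convention "T1" volume for the cyst) with label
masks. The default grid is 192 x 192 x 20 voxels at 0.6 x 0.6 x 6.0 mm —
the working spacing to which the pipeline resamples all inputs — giving a
115 x 115 x 120 mm field of view. Axis 1 is anterior-posterior, axis 2
superior-inferior (both in-plane), axis 3 left-right (through-plane).

Organs are ellipsoids with fixed millimetre anatomy (uterus semi-axes
15 x 22 x 14 mm centred mid-pelvis; bladder 13 x 17 x 12 mm anteriorly;
rectum 8 x 24 x 9 mm posteriorly; two ovaries 9 x 11 x 8 mm
posterolaterally), jittered per sample by ~5% in size and ~1 mm in
position. The sizes are roughly two-thirds anatomic scale so that the full
configuration, including a rectum displaced by adhesion, fits the field of
view with margin. Tissue intensity means are fixed on a 0-1 scale
(background 0.10, plaque 0.35, rectum 0.45, uterus 0.60, ovary 0.70,
bladder 0.90; cyst 0.85 against 0.15 on the T1 grid) with additive Gaussian
noise (default SD 0.05). The contrast ordering is a free design choice —
the source protocols do not constrain it — and it intentionally leaves the
plaque/rectum/background contrasts close enough that plaque segmentation
remains the hardest class, as it is on real data.

**The plaque.** The depth-measurement procedure (below) measures the
perpendicular distance between two parallel supporting lines anchored on
the plaque-uterus contact chord. On a *curved* posterior surface, a
constant-thickness crescent would measure thickness *plus* the sagitta of
the contact arc — several millimetres for realistic curvatures — so
constant thickness alone does not make truth analytic. The phantom
therefore flattens the posterior uterine surface where the plaque attaches
(a plane cut 3 mm anterior of the posterior pole) and grows the plaque as a
slab of constant thickness from that facet. For a planar contact the
supporting-line distance equals the slab thickness exactly, making the
ground-truth depth analytic by construction. The facet plane is snapped to
a voxel-footprint boundary and the slab is rasterized by *any-coverage*
(a voxel row belongs to the slab if the slab intersects its footprint), so
the rasterized slab spans exactly `ceiling(depth / 0.6)` voxel rows: the
measured depth is then `0.6 * ceiling(depth / 0.6)`, within one in-plane
voxel of truth for every depth, and sub-voxel slabs never vanish.

**The cyst.** The OEC is an ellipsoid with user-specified in-plane axes, a
16 mm through-plane semi-axis, and a random in-plane rotation; its centre
is snapped to a slice centre so the largest cross-section lies exactly on a
slice. Ground-truth volume is recorded as the voxel-counting volume of the
rasterized mask — the quantity the volume-change pipeline measures — since
the 6 mm slice sampling quantizes any analytic-volume comparison by a few
percent. Pre/post surgical pairs shrink the cyst volume by a random factor
in [0.1, 0.9] (axes scale by the cube root).

**Adhesions.** Each of the seven locations (left ovary-rectum, right
ovary-rectum, left-right ovary, uterus-left ovary, uterus-right ovary,
uterus-rectum, uterus-bladder) is drawn per patient as Bernoulli with
default prevalences (0.38, 0.37, 0.16, 0.73, 0.66, 0.62, 0.06) matching the
positive-sample rates of the study population the package emulates. A
flagged location deforms both named organs: each is stretched by 1.35 along
the inter-organ axis (and shrunk by 0.95 perpendicular to it), the apposed
surfaces are flattened by a 1.5 mm plane cut, and the movable organ is
translated until the surface gap along the centre line is ~0.5 mm. The
deformation thus encodes the adhesion in the organs' *shapes* — reduced
sphericity, increased elongation, local flattening — which is exactly the
signal the shape-radiomics classifier is designed to read; gap closure
additionally satisfies the geometric definition of adhesion. Overlaps that
arise after translation are resolved by a fixed rasterization priority
(uterus first; the plaque overwrites any non-uterus tissue in its slab, and
the generator verifies the slab still spans its full depth, rejecting the
spec otherwise).

What the phantoms do *not* emulate: MR physics (bias fields, coil
profiles), motion, uterosacral-ligament lesions, plaques away from the
posterior uterine surface, and curved plaque-uterus interfaces. Passing
tests therefore demonstrate correctness of the *measurement and learning
machinery* on geometry with known truth — not clinical performance on
patient MRI.

## Preprocessing and inference contracts

Volumes are z-normalized (mean 0, SD 1; constant volumes are rejected) and
resampled to 0.6 x 0.6 x 6.0 mm with trilinear interpolation (nearest
neighbour for masks), preserving physical extent. Training augmentation
applies, in order: random zoom in (0.9, 1.2); a random monotone intensity
warp (a Hyman-monotone piecewise-cubic map of the normalized intensity
range, blended with the identity by a strength parameter — monotonicity
preserves intensity ordering, which is all a histogram warp may break);
an additive offset drawn from (-0.1, 0.1) of the image SD; and Gaussian
noise N(0, 0.1). Whole-volume inference tiles the volume with 384 x 384 x
24-voxel patches at 50% overlap and averages overlapping probabilities with
uniform weights; the overlap fraction and uniform weighting are package
choices (Gaussian-weighted stitching is a common alternative; for the
linear predictors used at desk scale the two are identical, and the
stitched prediction of any voxelwise predictor equals its full-volume
application exactly).

## Training losses

For segmentation the package implements focal loss (mean of
`-(1-p_t)^gamma log p_t`, gamma = 2 by default, probabilities clipped at
1e-7), soft Dice loss (one minus the mean over foreground classes of
`2*sum(p*g) / (sum(p)+sum(g))`; a class empty in both prediction and target
counts as perfect), and a signed-distance boundary loss: the mean over
voxels of predicted foreground probability times the signed Euclidean
distance (mm, via an exact separable distance transform honouring
anisotropic spacing) to the target boundary, negative inside. Focal and
Dice combine 1:1 by default; the boundary term (weight 1.0, configurable)
is switched on for cyst segmentation, where it sharpens poorly expressed
boundaries. The focal gamma and the boundary weight are not pinned by the
source protocol; 2.0 and 1.0 are the conventional defaults and both are
exposed in `loss_config()`.

**The toy backbone.** The package deliberately does not reimplement a deep
segmentation network. The training and ensembling contracts are exercised
by a pluggable desk-scale backbone: a softmax voxel classifier over seven
per-voxel features (bias, intensity, two Gaussian-smoothed scales, and
normalized coordinates), trained by full-batch gradient descent on the
combined loss with a backtracking line search, which makes the recorded
training loss non-increasing by construction and reproducible under a
seed. Anything mapping a patch to per-class probabilities plugs into
`sliding_window_predict()` and `ensemble_predict()` (ensembles average
member probabilities voxel-wise; members differ by initialization seed).
On the demo cohort this backbone reaches per-organ Dice overlaps of
roughly 0.78-0.85 while plaque remains near zero — an honest reflection of
plaque being by far the hardest structure.

## Plaque morphometry

Per through-plane slice: (1) plaque contour pixels within a contact
distance of the uterus boundary form the contact set; (2) the line through
the two extreme contact points is the local surface direction; (3)
translating its intercept gives the two supporting lines enclosing every
plaque pixel (pixels enter as area elements via their corners, matching
the voxel-footprint rasterization); (4) depth is the perpendicular
separation of the supporting lines. The maximum across slices is the
reported depth; severity is none / mild (< 5 mm) / severe (>= 5 mm), the
5 mm boundary belonging to severe. The contact distance defaults to 1.5
in-plane voxels (0.9 mm on the working grid): with a 2-voxel reach the
contact band is two pixel rows thick and the extreme-point chord can tilt
by one pixel across the band's width, biasing every depth upward by about
one pixel; a 1.5-voxel reach keeps the band one row thick and removes the
bias. For strongly curved contact surfaces the chord is an approximation;
the phantom's planar facet makes it exact there, and rotation-invariance
is verified separately on rotated synthetic geometry.

Cyst axes come from a direct least-squares conic fit to the 8-connected
contour of each slice, rescaled so the fitted ellipse's area equals the
pixel-count area (compensating the half-pixel inward bias of contour-pixel
centres); per lesion (26-connected components, largest first) the slice
with the largest fitted-ellipse area is reported. Volumes are
voxel-counting volumes (count x 2.16 mm³ at the working spacing); volume
change is post minus pre.

## Shape radiomics

Fourteen features per organ: elongation and flatness
(`sqrt(lambda2/lambda1)`, `sqrt(lambda3/lambda1)` from the population
covariance of physical voxel centres), the three principal axis lengths
(`4*sqrt(lambda)`), maximum 2D diameters per orthogonal plane family and
the maximum 3D diameter (largest pairwise boundary-voxel distances), mesh
and voxel-counting volume, sphericity (`(36 pi V^2)^(1/3) / A` with mesh V
and A), surface area, and surface/volume ratio. The mesh is built by
marching tetrahedra on the 0.5-level of the padded mask after Gaussian
pre-smoothing with sigma = 1 voxel (halved automatically for structures
too thin to survive it): meshing the raw binary staircase overestimates a
sphere's area by 8-9% and caps sphericity near 0.92, while the smoothed
isosurface recovers area and volume within 1% and sphericity 0.995 on a
12 mm digitized ball. Feature vectors concatenate uterus, bladder, rectum
and ovary (left and right merged — the extraction target is one "ovary"
structure) into 56 named values; absent organs yield NA features plus a
missingness flag, and classifiers impute training-set medians. Reference
values for the oracle tests were computed once with an independent
Python implementation (numpy/scipy/scikit-image, marching cubes for the
mesh) on 20 seeded random blobs and frozen as a CSV fixture; the two
implementations agree within 0.2% despite using different meshing
algorithms in different languages.

## Adhesion classification

One gradient-boosted tree binary classifier per location (7 independent
models rather than one multi-label model, keeping per-location prevalence
and thresholds independent), with small-data-safe defaults: 200 trees,
depth <= 4, learning rate 0.1, no early stopping. Evaluation is 5-fold
cross-validation grouped by patient — all of a patient's images share a
fold, eliminating identity leakage — and stratified by patient-level label
(round-robin assignment after a seeded shuffle; grouped-only with a
warning when one class is absent). Out-of-fold probabilities are pooled,
thresholded at 0.5 (no threshold is prescribed by the source protocol),
and summarized as recall, precision and F1 with 95% percentile-bootstrap
confidence intervals over 2000 resamples of the pooled predictions — the
bootstrap is the package's choice of CI construction. A permutation null
(labels shuffled across patients, full CV re-run) provides the
chance-level F1 distribution; on phantom cohorts the true-label F1 exceeds
the null's 95th percentile by a wide margin.

## Evaluation stack

Dice similarity defines both-empty pairs as 1, flagged so summaries can
exclude them. Detections are axis-aligned half-open boxes per 26-connected
component; matching is greedy in descending confidence, each prediction
claiming the unmatched truth of highest IoU when IoU >= 0.01 — the
threshold is deliberately permissive because lesion shape varies strongly
in 3D, and "exceeded 0.01" is implemented as >= 0.01. Average precision
integrates the precision-recall step curve (`sum(dR * P)`); with one
lesion class, mAP = AP, and the curve's operating point at any confidence
cut yields the (recall, precision) pair. Whether the source protocol
averaged AP over multiple IoU thresholds is unspecified; the package
implements single-threshold AP and exposes the threshold. Reader
statistics: sensitivity per reader with the undefined-when-no-positives
convention, and unweighted Cohen's kappa (binary for adhesions, ternary
none/mild/severe for plaque; two identical constant raters are defined as
kappa 1 with a degeneracy flag).

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 200 phantoms at the
default 0.6 mm grid for depth recovery; a 200-sample cohort at a 1.2 mm
in-plane grid (same anatomy, coarser sampling) for adhesion
cross-validation, where shape features are measured; 20 random 40-cube
blobs for the shape-feature oracle; 500 random instances of up to 4 x 4
boxes for the detection oracle; and a 50-phantom demo cohort on 64 x 64 x
12 grids at 1.8 x 1.8 x 10 mm (identical field of view, coarser voxels)
with 100 training epochs. These sizes were chosen so each stage exercises
its full contract at single-CPU scale. Degenerate inputs have defined
behaviour throughout: constant volumes, empty masks, sub-5-point contours,
single-class training folds and zero-positive truth tables all raise
informative errors or flagged NA values rather than silent numbers.

## Known limitations

Plaque depth assumes the lesion contacts the posterior uterine surface;
detached or ligamentous lesions are out of scope. The chord construction
under-defines the surface direction for strongly curved contacts. The toy
backbone is a linear classifier and will not approach deep-network
segmentation quality on real data; it exists to make the loss, ensembling
and inference contracts testable. Phantom adhesion effects are strong and
shape-borne by construction — real adhesion signal is weaker and partly
textural, so classifier recovery on phantoms bounds machinery correctness,
not clinical accuracy.
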