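---
title: "Measuring muscle architecture from longitudinal ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring muscle architecture from longitudinal ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musarch)
```

## The measurement problem

In a longitudinal B-mode scan of a pennate muscle (biceps brachii, medial
gastrocnemius, tibialis anterior), the muscle is bounded by two bright
fibrous sheets — the superficial and deep aponeuroses — with the fascicles
visible as oblique bright stripes between them. Three architecture
parameters drive most clinical and biomechanical use of these images:

* **muscle thickness** $d$ — the perpendicular distance between the two
  aponeuroses, averaged along the muscle;
* **pennation angle** $\theta$ — the acute angle between a fascicle and the
  deep aponeurosis;
* **fascicle length** $L_F$ — the fascicle extent between the aponeuroses,
  estimated trigonometrically as $L_F = d / \sin\theta$.

`musarch` implements the full measurement chain: segmentation of the
aponeuroses with a compact attention U-Net (bypassable by supplying a label
mask), refinement of the predicted mask into two clean single-valued curves,
centerline-based thickness, unsupervised fascicle extraction, and the angle
and length estimates, plus the agreement metrics used to compare automatic
with manual measurements (RMSE, ICC(2,1), Bland–Altman).

Because no clinical images ship with the package, every stage is validated
against a **synthetic phantom generator** whose geometry is known exactly;
the phantom module is first-class, tested code.

## The phantom generator

`phantom_spec()` describes a phantom: two polynomial curves of degree
$\le 2$ (row as a function of column — the same family the refinement stage
fits), a band thickness of 3–7 px for the bright aponeuroses, oblique
fascicle stripes at a known angle $\theta^\*$ measured against the deep
curve's *local tangent*, a pixel spacing in mm/px, optional blanked column
intervals that emulate segmentation gaps, and multiplicative speckle-like
noise (`pixel * (1 + level * N(0,1))`, clipped to [0, 255]).

Conventions chosen once and shared by all modules:

* grids are numeric matrices indexed `[row, col]`, 1-based, rows increasing
  downward;
* segment orientation is the angle against the +column axis with rows
  increasing downward, folded to [0, 180); the canonical fascicle descends
  to the right (small positive orientation). Biceps brachii images, where
  fascicles ascend to the right, are flipped horizontally before extraction
  and results are mapped back, and the lower tibialis anterior compartment
  is handled the same way.
* `fascicle_spacing_px` is the *perpendicular* separation between stripes
  (anchors on the deep curve advance by `spacing / sin(theta)` columns);
  with horizontal anchor spacing, shallow-angle stripes would overlap and
  merge into one blob, which no extraction method could separate.

The ground truth carries the exact mean perpendicular inter-curve distance
(computed by symmetric dense nearest-point sampling), the stripe angle, and
the implied fascicle length, which satisfies
$L_F \sin\theta^\* = d$ to $10^{-9}$ relative error by construction.

What the phantom does **not** emulate: point-spread blur, attenuation and
depth-dependent gain, curved fascicles, out-of-plane fascicle portions, and
real speckle correlation. Passing the recovery suites therefore shows the
geometry pipeline is correct and noise-tolerant at moderate speckle levels;
it does not certify performance on clinical images.

## Aponeurosis segmentation (attention U-Net)

The segmentation stage follows the published recipe: 256×256 inputs, 300
epochs, batch size 8, Adam with a stepwise learning-rate decay, a weighted
soft-Dice loss, and augmentations including vertical flips, rotation,
scaling and a boundary-aware variant of random erasing that samples patch
centres preferentially on the aponeurosis label, emulating the band gaps the
refinement stage must repair. Width and input size are configuration
parameters with small defaults so that smoke-scale training runs on a CPU;
the architecture family (encoder–decoder with an attention gate on the skip
connection) is fixed, its size is not.

The network is implemented directly on BLAS matrix operations (im2col
convolutions with hand-written backward passes). That keeps the package
dependency-free, bit-deterministic under a seed, and fast enough to overfit
four 64×64 phantoms to training Dice > 0.9 in well under ten CPU-minutes —
the package's segmentation smoke test. Unspecified training details are
deliberate package choices: Dice class weights default to inverse class
pixel frequency on the training set; the learning rate drops ×0.1 at 60%
and 85% of the epoch budget; erasing patches are 4–32 px per side. Classes
with zero mass in both prediction and target are excluded from the weighted
Dice mean, which makes the loss exactly 0 at the one-hot target and exactly
1 for an everywhere-wrong one-hot prediction.

The whole stage is bypassable: every downstream function accepts a label
mask directly, and `measure_image()` treats a supplied mask and a model
prediction identically.

## Mask refinement

Predicted masks fail in two ways: gaps across a boundary, and spurious
small structures. `refine()` implements the repair: 8-connected component
analysis; the two largest components become the aponeurosis candidates; for
each candidate, remaining fragments lying **along its x-axis band** are
skeletonised (Zhang–Suen thinning) together with the candidate and a
degree-2 polynomial is fitted jointly to the skeleton points; missing
columns are filled from the fit, kept columns are smoothed by replacing
points deviating more than 3 px from it; everything unused is discarded as
artifact. Candidates are labelled superficial/deep by mean row, and a
crossing pair is a hard error rather than a silent repair.

"Along the x-axis" is operationalised as: the fragment's column interval
intersects columns missing from the candidate *and* its mean row is within
±height/8 of the candidate's extrapolated row there — pure column overlap
would absorb fragments of the other aponeurosis. A fragment acceptable to
both candidates goes to the vertically closer one. The joint
candidate+fragment fit (rather than fragment-only) was chosen because the
fill must be continuous with the candidate on both sides of a gap. With
fewer than 3 distinct columns the fit degrades to linear; with fewer than 2
the candidate is returned unfilled with a warning flag. The tibialis
anterior central fascia (label 2) runs through the same completion as a
single-candidate variant.

## Thickness

A centerline is drawn midway between the curves (per shared column); at
each centerline sample a chord is cast perpendicular to the local tangent
(central differences) until it meets each curve, with sub-pixel
intersection against the curve polylines; chords leaving the shared column
range are dropped. The centerline is divided into **five equal-arc-length
sectors**; the reported thickness is the mean of the sector means, which
both honours the sector decomposition and uses every chord. Pixel lengths
convert to mm by one isotropic scale factor; a missing or anisotropic
spacing is an error, never a silent assumption of 1.0.

## Fascicle extraction

Inside the region bounded by the curves (inset 4 px to exclude the bands
themselves) the stage runs: CLAHE (clip limit 2, 8×8 tiles, single-tile
fallback for small regions); a multiscale Hessian ridge filter at scales
{1.5, 2.5, 3.5} px (bracketing stripe widths, max over scales); 2-means
binarisation on the response, with deterministic quantile-initialised
centers; removal of structures under 30 px; per-structure skeletonisation
and total-least-squares line fitting (principal axis, so near-vertical
lines are handled); collinearity merging; dominant-orientation selection by
1-D k-means over orientations (k = 3 separates fascicle, noise and residual
band orientations; the cluster with the largest **total length** wins, and
the dominant orientation is its length-weighted mean); finally each
retained segment is extended along its line to the region boundary, and
while any two extended lines cross strictly inside the region, the line
deviating most from the median orientation is deleted (median recomputed
per deletion, deviation ties drop the shorter line).

Numerical choices that required a decision:

* **Response floor.** The masked ridge response is normalised only if its
  raw maximum exceeds $10^{-3}$; below that the region is declared empty.
  Contrast enhancement shifts a constant region by ~2 intensity levels,
  and without the floor that numerical dust would binarise into
  "structures". The response is also zeroed within `3*max(scale)` px of
  the region boundary, where the bright bands outside bleed into the
  Hessian.
* **Merge criteria.** Segments merge when at least two of the three
  collinearity criteria hold: extensions intersect inside the image; one
  midpoint is upper-left of the other; orientations differ by < 5°
  (strict). Two tolerances make these robust on a pixel grid: parallel
  lines count as intersecting only when coincident within 2 px, and
  upper-left requires a 2 px margin in both coordinates. A merge is
  accepted only if the merged segment's orientation stays within 5° of
  both parents — connecting pieces of one line cannot change its
  direction, and without the guard, edge-clipped parallel fascicles that
  happen to satisfy the other two criteria fuse into long spurious
  segments that would dominate the total-length vote.
* Orientations are clustered directly (not circularly): after the
  muscle-specific flips the fascicle orientations sit well inside (0°,
  90°), far from the 0/180 wrap.

## Pennation angle and fascicle length

Each extended fascicle line is intersected with the deep curve by marching
its polyline; if the crossing falls outside the image, the deep curve is
extended linearly from a fit to its last (or first) 25% of columns and the
intersection taken on the extension, flagged in the report. The per-fascicle
angle is the acute angle between the line and the deep tangent at the
intersection; fascicles within 0.5° of the tangent are flagged parallel and
excluded. The reported $\theta$ is the **median** over fascicles — the
source method reports a single dominant angle without an aggregation rule,
and the median resists the occasional outlier line. $L_F = d/\sin\theta$ is
then exact by definition, so every report satisfies
$L_F \sin\theta = d$ to $10^{-9}$ relative error.

The error in $L_F$ grows as $\theta \to 0$ at rate
$\partial L_F/\partial\theta = -d\cos\theta/\sin^2\theta$: at
$\theta = 10°$ and $d = 16$ mm, one degree of angle error is ≈ 9 mm of
length error. This is intrinsic to the trigonometric estimate (it is why
length results degrade for near-parallel biceps fascicles), and the test
suite checks that the measured $L_F$ error is bounded by this sensitivity.

## Agreement metrics

Dice and IoU (`dice = 2|A∩B|/(|A|+|B|)`, with the empty-vs-empty pair
defined as 1.0 for degenerate phantom cases), ICC(2,1) computed from the
two-way random-effects mean squares
$(MS_R - MS_E)/(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$,
RMSE, and Bland–Altman bias with 95% limits of agreement
(bias ± 1.96·SD of the differences, SD with the $n-1$ denominator).

## Validation suites and problem sizes

Two fixed 50-phantom suites validate the chain end to end, sized so the
whole validation runs in a few CPU-minutes:

* **thickness**: 480×460 px phantoms at 0.1 mm/px, thickness ramped
  5–35 mm, curve shapes cycling flat/linear/quadratic, speckle level 0.2,
  and two gap intervals punched into one aponeurosis band per phantom (the
  failure mode the refinement is designed to repair; with both bands
  fragmented the top-2-by-area candidate selection is ill-posed by
  construction). Recovery target: RMSE ≤ 0.4 mm, the human-vs-automatic
  discrepancy the method reports on clinical data.
* **pennation**: 480×420 px phantoms, angles ramped 8–35°, thickness
  15–25 mm, same curve family and noise. Recovery target: RMSE ≤ 2.22°.

Mirror-symmetry properties (horizontal flip leaves thickness and pennation
unchanged) hold to pixel-level accuracy — about 0.01 mm and 0.05° — rather
than floating-point accuracy, because Zhang–Suen thinning passes are
direction-ordered; this is documented behaviour, not noise.

## Known limitations

* The segmentation stage is validated at smoke scale (overfitting four
  phantoms); no claim is made about clinical-image Dice.
* Fascicles are modelled as straight lines; curved-fascicle tracking and
  Radon/wavelet orientation methods are out of scope.
* DICOM reading is not included; PNG/TIFF plus an explicit pixel spacing
  (or the phantom's JSON sidecar) are the supported inputs.
* The thickness of a tibialis anterior muscle is measured across the whole
  muscle by default; per-compartment measurement is available by passing
  the compartment curve pair explicitly.
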