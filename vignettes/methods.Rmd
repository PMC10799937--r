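---
title: "Mapping individual dead trees: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping individual dead trees: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snagmap)
```

## The problem

Standing dead trees (snags) are a key signal of forest stress — drought,
bark-beetle outbreaks, disease and fire all leave dead crowns that are
visible in sub-metre aerial imagery. Counting dead trees *individually*,
rather than mapping burned or degraded stands wholesale, matters because a
large share of mortality is scattered: single dead trees or small groups
that coarse (e.g. 30 m) change products systematically miss. snagmap
implements a complete tree-level pipeline: detect individual dead crowns in
4-band (RGB + NIR) imagery at 0.6 m ground sample distance, measure their
geometry, classify their decay stage from colour, aggregate them into
management-scale grid products with bias correction, and attribute probable
damage agents from survey polygons.

## Instance segmentation with ordinal energy levels

Touching crowns are the central difficulty: a semantic segmentation of
"dead pixels" merges neighbouring dead trees into clumps and undercounts.
snagmap uses a deep-watershed formulation. Instead of a single dead/alive
mask, the network predicts a quantised *energy level* per pixel — the
distance to the nearest crown boundary, binned into $K$ levels (level 1 is
the boundary ring, level $K$ the crown core, 0 background). The classic
marker-based watershed then floods the energy surface downhill from the
level-$K$ cores, and touching crowns split at the energy valley between
their cores.

The levels are predicted *ordinally* rather than as independent softmax
classes: the head has one sigmoid unit per level and a pixel can only carry
level $j$ if it also carries level $j-1$. Decoding enforces this with a
cumulative product, $q_j = \prod_{i \le j} p_i$, and the decoded level is
the largest $j$ with $q_j \ge \tau$ (threshold $\tau = 0.5$ by default).
The ordinal scheme guarantees that energy decreases monotonically from
core to boundary, prevents holes inside predicted crowns, and makes the
level sets nested, so the watershed markers (connected components of the
top non-empty level in each basin, 8-neighbour connectivity) are
well-defined.

Encoding choices (the quantisation rule is not something a published
number fixes, so they are configuration):

* `energy_levels` ($K$): default 5. With 0.6 m pixels and crown radii of
  1.5–4 m, a crown core is 2–7 px from the boundary; five levels keep each
  ring at least one pixel wide.
* `energy_normalisation`: `"instance"` (default) scales each instance's
  distances by that instance's maximum, so small and large crowns both
  reach level $K$; `"absolute"` bins raw pixel distance one level per
  pixel. Instance normalisation is the default because marker existence
  for every crown is what the watershed needs.
* Single-pixel instances receive level $K$ directly.
* Distances are Euclidean on pixel centres (the distance transform is
  EBImage's).

## The network and its loss

The segmentation backbone is a compact UNet-style encoder–decoder with
batch normalisation after every convolution: two 3×3 blocks at full
resolution, one block after each of two 2×2 max-pools, a mirrored decoder
with nearest-neighbour upsampling and skip concatenation, and a 1×1
ordinal head. The `small` preset (base width 8, ≈18k parameters) trains in
minutes on one CPU; `wide` doubles every width. The implementation stores
feature maps as pixel-major matrices with a one-pixel zero border per
sample, which turns every 3×3 tap into a contiguous submatrix GEMM — this
is why a from-scratch CPU implementation is practical. Analytic gradients
for every layer are verified against finite differences in the test suite.

Training minimises the Focal Tversky loss per energy level,

$$\mathrm{TI}_j = \frac{TP_j + s}{TP_j + \alpha FP_j + \beta FN_j + s},
\qquad L = \frac{1}{K}\sum_j (1 - \mathrm{TI}_j)^\gamma,$$

with $(\alpha, \beta, \gamma) = (0.4, 0.6, 2)$ and smoothing $s = 1$. Here
$\alpha$ weights false positives and $\beta$ false negatives, so the
asymmetric defaults trade the two error types off differently from Dice,
and $\gamma = 2$ focuses the gradient on poorly fit levels — useful when
dead pixels are a small minority of each patch. At
$\alpha = \beta = 0.5, \gamma = 1$ the loss reduces exactly to soft Dice,
which the tests assert against an independent implementation.

Optimisation uses Adam at learning rate $3 \times 10^{-3}$ (the optimiser
family is standard; the rate is this package's choice, set where the
per-level loss reaches convergence within the 15-epoch desk-scale budget,
and exposed as an argument).
Model selection is *not* by loss: at the end of every epoch the validation
patches are run through the full decode (probabilities → ordinal
enforcement → watershed → instance count) and the checkpoint with the
lowest validation count MAE is kept. Counting is the quantity of interest,
and the test suite asserts the selected epoch is the argmin of the
recorded history.

Augmentation applies, per patch and with probability 0.35 each (the
configured range is 0.2–0.5): a geometric affine warp (rotation ±15°,
shear ±0.2, scale 0.9–1.1) applied jointly to image and instance labels
with the ordinal target re-encoded from the warped labels, emulating
off-nadir distortion; and spectral gain/offset jitter applied to the image
only. Training sets include ≈12% background-only control patches
(`control_fraction`).

Prediction on tiles larger than the network patch uses overlapping patches
whose per-level probabilities are blended with centre-weighted averaging
(weights ramp to zero at patch edges) before ordinal enforcement, which
suppresses seam artefacts; a stitching-consistency test requires ≥99%
pixel agreement between whole-tile and tiled prediction.

## Crown geometry

Each watershed instance becomes one crown record: interior holes are
filled before measurement, area is pixel count × pixel area, the centroid
is the mean of pixel centres, and the moment-equivalent ellipse gives
semi-axes $a = 2\sqrt{\lambda_1}$, $b = 2\sqrt{\lambda_2}$ (eigenvalues of
the second-order central moment matrix — exact for a uniform ellipse).
Eccentricity $e = c/a = \sqrt{1 - (b/a)^2}$, with $c$ the focal distance,
quantifies elongation: circular crowns give $e \approx 0$, view-angle
distortion stretches crowns towards $e \to 1$. Components smaller than
`min_pixels = 8` are dropped as speckle (a package choice; the detection
stage of the source method reports no explicit floor, so it is exposed in
configuration). Degenerate single-pixel regions get $a = b =$ half a
pixel and $e = 0$; one-pixel-wide shapes are floored at a quarter pixel of
minor axis so $e$ stays below 1.

For distortion QA, the median eccentricity of crowns larger than 50 px
(18 m² at 0.6 m GSD) is gridded at 500 m, and cells with median $e > 0.8$
are flagged; area-derived products should be treated cautiously there.

## Mortality staging from crown colour

A recently dead ("brown-stage") crown retains dried foliage and appears
brown-red; a long-dead ("grey-stage") snag has shed foliage and appears
grey-white. Staging works on the mean RGB of each crown after a one-pixel
inner erosion (mixed edge pixels would otherwise bias the mean; crowns
that erode to nothing fall back to the full mask with a warning). The mean
colour is converted to hexcone HSV ($H, S, V \in [0,1]$) and scored:

$$H_g = 1 - \frac{|H - 1/3|}{1/6}, \qquad
  H_r = \frac{1/2 - H}{1/6} - 2,$$

$$X_c = \frac{C^{x} - 1}{C - 1}$$

with $x = H_g$ (green), $H_r$ (brown), $1-S$ (grey), $1-V$ (background)
and constants $(C_g, C_r, C_y, C_b) = (5, 5, 10^7, 10^4)$. Hue-based
scores are zero when their hue term is negative or when $S = 0$ (hue
undefined); $X_{grey}$ is zero when $V = 0$ (saturation undefined — pure
black is background); red hues above $H = 5/6$ wrap to $H - 1$ before
computing $H_r$, since reds live at both ends of the hue circle. The crown
takes the argmax class; exact ties resolve grey > brown > green >
background, conservative with respect to recent-mortality claims. Crowns
scored green or background are retained but flagged as non-dead-stage for
QA. The bounded form $(C^x - 1)/(C - 1)$, which maps $[0,1]$ onto
$[0,1]$, is used for all four scores for internal consistency; the
alternative reading $C^{x-1}/(C-1)$ of the two hue scores is available as
`literal_exponent = TRUE`.

The per-cell brown-stage share applies a noise rule: cells whose brown
count is exactly one are set to 0% brown (single brown calls are most
often misclassification); `drop_single_brown = TRUE` drops those cells
from the table instead of zeroing them.

## Grid products and count bias correction

All crown-to-cell assignment is by centroid on half-open, axis-aligned
grid cells anchored at the raster's top-left corner (a centroid on a
shared edge lands in exactly one cell; crowns spanning cells are not
split, preserving the meaning of dead-canopy percent). Products: raw and
bias-corrected counts (30/100/240 m), percent mortality against a
user-supplied live-tree baseline (240 m), dead-canopy percent and median
crown size (100 m), brown-stage percent (100 m), median eccentricity
(500 m), a cluster-size profile of the raw 30 m counts (isolated trees are
the $k = 1$ cells), and a three-band hotspot composite (count, brown %,
median size), each band rescaled between its own 2nd and 98th percentiles
over valid cells.

Counting networks selected per patch systematically under- or over-count;
summed over a large area that patch-level bias compounds. The mean-error
model adds $\mathrm{ME} = F \cdot \overline{(Y^{obs} - Y^{pred})}$ per
hectare (with $F$ the patch-to-hectare scale factor) to every cell of the
gridded counts. Two invariants are enforced: 30 m grids are never
bias-corrected (they feed tree-level analyses such as the cluster
profile), and the correction changes the regional total by exactly
$n_{cells} \times \mathrm{ME} \times$ cell area — a bookkeeping identity
the tests assert.

## Damage-agent attribution

Aerial detection surveys (ADS) deliver polygons with up to three coded
damage agents and a survey year; fire perimeters carry a year. Because
surveys re-report mortality annually, overlapping survey polygons resolve
to the agents of the *later* year; equal years take the code-sorted union
truncated to three (the precedence rule leaves equal years undefined, so
the union is this package's documented choice). A fire polygon adds the
`fire` code wherever its year is not earlier than the governing survey
year — an older fire cannot explain later-reported mortality — and
fire-only areas attribute to `fire` alone; a survey's three agents plus
fire may therefore carry four codes. Crowns take the agents of the
resolved partition at their centroid (a tree has one death and one
location), and level-4 codes roll up through a user-editable CSV hierarchy
(level 4 → 3 → 2 → 1); a ten-code demo hierarchy ships with the package.
The implementation sweeps layers with commutative max/union semantics, so
the result is independent of layer order; tests verify equivalence with a
brute-force per-centroid oracle that applies the two rules pairwise.

## Evaluation protocol

Counts: MAE, relative total error
$\mathrm{rTE} = |\sum(Y^{obs}-Y^{pred})| / |\sum Y^{obs}|$, and percent
count bias $100 \sum (Y^{obs} - Y^{pred}) / \sum Y^{obs}$ — positive bias
means underestimation, stated explicitly in outputs because the sign
convention is easy to invert silently. MAE and rTE are deliberately
complementary: MAE measures per-patch error, rTE lets opposite errors
cancel, and the tests pin the case where MAE is large while rTE is zero.
Masks: per-class pixel IoU and mIoU; a class absent from both rasters
scores 1 by default (a control patch predicted empty is a success), or can
be dropped.

Field comparisons mirror ground-truthing practice: predicted crowns are
buffered by 6 m to absorb image georeferencing error; an observed tree
point matches if it falls in any buffered crown; an observed crown polygon
matches if buffered predictions cover more than half its area (computed by
fine rasterisation, 0.25 m default); plot counts compare observed counts
(optionally filtered to DBH ≥ 40 cm when census data carry diameters)
against predicted centroids inside the 6 m-buffered plot polygon.
Tree-level matching is one-to-many — the protocol does not impose a
bijection. Both the matched percentage and its complement are reported,
since "bias" at tree level is the unmatched share.

## The synthetic scene generator

Every stage above is exercised end to end on synthetic scenes with
exhaustive truth, generated at 0.6 m GSD. What it emulates:

* crowns as filled ellipses with per-crown semi-major axis drawn from
  lognormal($\log 2.2$, $0.25$) metres with a 1.5 m floor and axis ratio
  0.7–1. The floor keeps the smallest crown at ≈11 px, above the 8 px
  speckle filter: simulated crowns represent *detectable* dead trees, and
  typical dead conifer crowns at this resolution are 3–8 m across;
* clustered and isolated placement: a configurable fraction of crowns is
  placed in touching clumps (centre separation 1.2–2.0 × the pair's mean
  radius — exactly the regime the watershed must split); isolated crowns
  are pairwise disjoint by rejection sampling, and placements that fully
  occlude a crown are re-drawn;
* colour: brown-stage crowns from a warm chromatic palette, grey-stage
  from a cool, slightly blue ash palette, live canopy green with high
  NIR, dead crowns with depressed NIR (chlorophyll loss). The palette
  boxes are constructed so that *every* colour in the box classifies to
  its own stage under the HSV scores — asserted in the tests — so staging
  accuracy on synthetic scenes isolates pipeline defects from palette
  ambiguity;
* a scene-level affine (shear 0.15, scale 0.9–1.1) applied consistently
  to image and truth, emulating off-nadir distortion, plus additive
  Gaussian band noise (sd 4 DN);
* companion fixtures: jittered field-survey points with configurable
  detectability, and overlapping agent/fire rectangles with years.

What it does **not** emulate: radiative transfer, shadows, terrain,
understorey structure, spatially correlated sensor noise, species
variation in crown colour, or crowns partially hidden by live canopy.
Passing the synthetic suite therefore demonstrates that the algorithms are
implemented correctly and the pipeline is internally consistent — not that
the shipped `small` network would reach operational accuracy on real
imagery, which requires real labels and a larger encoder.

## Numerical choices and degenerate inputs

* Watershed connectivity is second-order (8-neighbour) throughout;
  flooding is synchronous minimum-label propagation, so ties go to the
  smallest marker label deterministically.
* The presence threshold $\tau = 0.5$ is the symmetric decision point on
  each sigmoid; exposed in configuration.
* Rasters store integers exactly (16-bit); floating-point layers are
  range-normalised into 32-bit TIFF with the range in the sidecar.
* Empty inputs (no crowns, empty masks, zero observed totals) return
  empty tables, all-zero maps, or NA where a ratio is undefined — never
  errors — except where the contract demands one (bias correction on a
  30 m grid, misaligned grids, missing CRS).
* All randomness flows from explicit seeds; training is deterministic for
  a fixed seed on a fixed BLAS, and two identically seeded runs are
  asserted identical in the tests.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale, chosen so
the whole suite completes on one CPU in well under half an hour: 100
synthetic scenes for the energy round-trip, an 18-point-per-channel RGB
cube sweep for staging, 1,000 simulated 0.1 ha patches for bias
correction, 100 random layered fixtures for attribution, and one
end-to-end training run of 200 patches of 128 × 128 px for 15 epochs with
an 8:1:1 split. The end-to-end thresholds (validation count MAE ≤ 1.5
trees/patch, dead-class IoU ≥ 0.5, mIoU ≥ 0.6) are targets for this
package's scaled-down synthetic setting, not published accuracies.

## Known limitations

* The `small` network is sized for CPU verification; operational use
  needs a larger encoder and real training labels.
* Crown-size distortion is flagged (eccentricity) but not corrected;
  correction would need per-image view-angle metadata.
* GeoJSON and sidecar-georeferenced TIFF are the interchange formats;
  there is no reprojection — all inputs must share one projected CRS.
* Pointwise (centroid) agent attribution ignores crowns straddling a
  polygon boundary; with 0.6 m crowns and survey polygons of hectares,
  the effect is marginal.
* The staging constants are taken as given; the package does not re-fit
  them, and reported staging accuracy on synthetic palettes does not
  transfer to real imagery.
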