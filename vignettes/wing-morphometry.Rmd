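---
title: "Wing morphometry with wingtrich: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wing morphometry with wingtrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingtrich)
```

## The measurement problem

An adult *Drosophila* wing is a flat, two-layered epithelium in which
every cell secretes exactly one hair (trichome). In a transmitted-light
photomicrograph taken with the condenser closed, each trichome shows a
small, distinctly darker base. Two quantities summarize the biology:

* **trichome density** (count per px² of tissue) — a proxy for cell
  density, hence cell size;
* **intervein region area** — the tissue between longitudinal veins,
  cross veins and the wing margin — a proxy for tissue growth.

In the standard assay a GAL4 driver misexpresses a transgene only in the
posterior compartment, and the posterior/anterior ratio of densities or
areas controls for slide-to-slide variation. wingtrich computes these
quantities reproducibly from script, with no interactive steps.

## Trichome detection: prominence-based maxima

Detection runs on the inverted image (bases are dark, so they become
peaks). The detector's definition, implemented exactly in C++:

* a **candidate** is a plateau — a maximal 8-connected set of
  equal-valued pixels with no strictly higher 8-neighbour;
* a candidate of value $v$ is **accepted** iff every 8-connected path
  from it to any strictly higher pixel contains a pixel of value
  $\le v - t$, where $t$ is the *noise tolerance*;
* each accepted plateau emits one point, its pixel centroid rounded to
  the nearest pixel (exact halves round toward the smaller row, then the
  smaller column);
* equal-valued accepted candidates that can reach one another above the
  floor $v - t$ collapse to one point (smallest centroid wins);
* a plateau touching the image border with no strictly higher pixel
  anywhere in the image is suppressed, so a perfectly flat field yields
  no points. Interior maxima that merely sit near the border are kept.

The tolerance $t$ is the one tuning parameter that matters; it is a
prominence threshold on the 8-bit intensity scale. The default of 10 is
the empirical operating point at which essentially all normal trichome
bases in a well-focused, high-contrast micrograph are marked; lowering
it recovers fainter structures at the cost of noise and dirt. All
counting operations run detection on the **full image** and then filter
points by the region of interest — cropping first would change
prominence comparisons near the crop border.

The test suite pins this definition to an independent, exhaustive
path-search oracle (literal BFS over all paths above the floor) on
hundreds of random 16 × 16 images at four tolerances; the two
implementations must agree exactly.

### Determinism

Every stage is deterministic: plateau discovery and flooding use fixed
scan orders, watershed ties resolve by synchronous wave fronts (below),
and the random-forest classifier both trains under a caller-supplied
seed and predicts by vote counts with a fixed tie-break (the stock
`predict` method breaks vote ties with the RNG, which would make
repeated segmentations differ). Counting the same region of the same
image twice always returns the same number — the property reported as
run-to-run precision by `scripts/acceptance.R`.

## ROI geometry

Squares are centered on the click point; odd sides sit symmetrically,
even sides extend one extra pixel down and right; a square that would
leave the image is an error (with the nearest valid center suggested).
Polygon vertices are continuous (col, row) points at pixel centers; area
is the shoelace formula; a detected point counts as inside by the
even-odd rule with boundary points included, so a partition of a polygon
assigns each interior point exactly once. Density is defined as
trichomes per px² of subtended area — the only dimensionally coherent
reading of "density per pixel".

## Seeded watershed spacing cells

For the spacing heat map, each detected trichome seeds one basin and the
inverted image floods in order of decreasing intensity. Within one
intensity level the fronts advance as synchronous geodesic waves; a
pixel reached in the same wave by two basins becomes a one-pixel
boundary (label 0). This plateau rule makes the partition symmetric for
mirror-symmetric inputs (the asymmetric alternative — first-come
scan-order flooding — silently biases cell areas). Cells are
4-connected, contain exactly one seed each, and together with the
boundary pixels tile the image exactly; cell area is the inverse of
local trichome density.

## Trainable vein segmentation

Segmentation classifies each pixel of a 512 × 380 working-resolution
copy (bilinear resize; the fixed size keeps feature scales comparable
across input resolutions) into vein+margin, intervein, or background.

Features, 15 per pixel: raw intensity; Gaussian-smoothed intensity at
σ ∈ {1, 2, 4, 8, 16}; gradient magnitude at σ ∈ {1, 2, 4}; differences
of Gaussians (1, 4) and (2, 8); larger and smaller Hessian eigenvalues
at σ ∈ {2, 4}. These are the standard trainable-segmentation defaults:
smoothers capture local brightness (membrane vs mounting medium),
gradients and Hessians capture the ridge-like veins, DoG captures
blob-like texture (the trichome speckle that distinguishes intervein
tissue from empty background at working resolution).

The classifier is a random forest — 100 trees, each on a bootstrap
sample with ⌊√15⌋ = 3 candidate features per split — requiring at least
50 labeled pixels per class. Three classes rather than two because
border-touching background must be distinguishable from vein/margin for
the particle-analysis border rule to work. After prediction, one 3 × 3
modal filter despeckles the class map (ties keep the center's class).

Particle analysis then takes 4-connected components of the intervein
class, fills holes, discards components under 200 px (at working
resolution) and components touching the border (background
leak-through), labels survivors 1..k in decreasing area order, and
upscales masks to source resolution by nearest neighbour (which cannot
invent phantom labels). The 200 px floor is chosen so the smallest real
intervein region survives on synthetic wings while specks do not; the
filters commute, which the suite checks against a brute-force region
filter on random maps.

The model serializes to a single portable RDS file with a format-version
field; user scribble masks are supported in place of generated labels.

## Heat maps

Both heat maps color a per-object value — intervein region area, or
spacing-cell area — normalized within `[value_min, value_max]` and
clamped. The default range is the observed per-image min/max
(zero-configuration); publication figures comparing genotypes should fix
the range explicitly so colors are comparable across images. The default
ramp is fire-like (black → blue → red → orange → yellow → white),
monotone in lightness so larger means hotter; the exact RGB stops are a
package choice, and only the ordering is meaningful. The optional legend
bar labels exactly `value_min` and `value_max`.

## The synthetic wing generator

The generator exists so that every stage has ground truth. It renders,
at a default 2080 × 1544 (the native resolution of the camera setup the
defaults emulate):

* a pale surround (mounting medium, grey 235) and slightly darker wing
  membrane (222) inside an elliptical blade;
* a margin ring and four longitudinal veins (quadratic curves) plus two
  cross veins at grey ≈ 115–125, partitioning the blade into seven
  intervein regions. Vein intensity carries a gentle proximal–distal
  ramp plus a one-grey-level deterministic dither, so even a noise-free
  wing has no large flat vein plateau (a flat plateau's centroid can
  fall off the vein and register as a false trichome inside tissue);
* trichomes at rate 0.0035 per px² of intervein area (≈ 80 in a 150 px
  square, matching manual counts in such fields), placed by a hard-core
  process (minimum spacing 10 px) that models the quasi-regular lattice
  of real wings — a pure Poisson process would overproduce accidental
  merges. Each trichome is a dark disk (base, grey 60, diameter 7 px)
  with a short brighter shaft;
* the two failure classes: a fraction of trichomes (default 0.02)
  duplicated at sub-diameter offset — the coincident dorsal/ventral
  class, which the plateau rule merges into one detection by
  construction — and a fraction (default 0.03) rendered at half
  diameter with only ~10 grey levels of contrast, so their prominence
  straddles the tolerance of 10 and detection becomes a near coin flip,
  as for real undersized trichomes;
* additive iid Gaussian noise (default sd 4) and optional dirt specks,
  added last.

Defaults equal the audit imaging conditions used by the acceptance
checks. With sd-4 noise, background excursions of ≈ 2.5 sd have
prominence near 10, so the detector necessarily marks thousands of
sub-threshold noise maxima across a full frame. This is faithful to
real usage — dirt and dust are counted inappropriately on real images
too — and is why density measurements are taken inside selected regions.
It also means detector *precision* on noisy synthetic frames is low by
design, while *recall* (the quantity the accuracy claims concern) stays
high.

What the generator does **not** emulate: optical blur and shading,
uneven illumination, wing folds and bubbles, true trichome shape and
polarity, and pigmentation differences. Passing tests therefore
demonstrate algorithmic correctness and the stated failure-mode
behavior, not robustness to every real-world artifact; low-contrast or
out-of-focus real images will do worse, as they do interactively.

`evaluate_detection` matches predictions to truth greedily in increasing
distance order, each point used at most once, within a 4 px radius
(about half a trichome-base diameter at the default scale).

## Numerical and degenerate-input choices

* 8-bit grayscale throughout; RGB converts by ITU-R 601 luminance;
  16-bit input rescales linearly per image.
* Bilinear resize with rounding; resize to the same size is the
  identity; constants stay constant.
* Coordinates are 0-based (row, col), origin top-left; a pixel is 1 px².
* A constant image has no detectable spots (border-plateau rule).
* Zero detected trichomes make `trichome_spacing_cells` an error that
  advises lowering the tolerance, not an empty partition.
* Degenerate polygons (< 3 vertices, self-intersecting, zero area) are
  rejected up front; a zero denominator density is an explicit error.

## Problem sizes in the tests

The suite validates the detector oracle on 16 × 16 images (where
exhaustive path search is cheap), runs full-size 2080 × 1544 wings for
the acceptance-grade checks (repeat-count precision, the fifteen-square
audit, segmentation IoU, density-ratio recovery), and uses 640 × 480 or
1040 × 772 wings for property sweeps such as monotone recall
degradation, where many wings must be generated. These sizes were chosen
so each property is tested at the smallest scale at which it is
meaningful.

## Known limitations

* The classifier generalizes across wings drawn from this generator;
  applying it to real micrographs requires retraining on real scribbles
  (supported via label masks).
* No sub-pixel localization and no trichome shape analysis; the
  detector reports one pixel per trichome base.
* Polygon ROIs assume simple polygons; holes require partitioning.
* The spacing heat map inherits detector errors: a merged coincident
  pair produces one oversized cell.
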