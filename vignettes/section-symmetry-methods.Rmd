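---
title: "Quantifying dorsoventral symmetry in limb cross-sections"
author: "SectionSymmetry authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dorsoventral symmetry in limb cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SectionSymmetry)
```

## The problem

Regenerated axolotl limbs that form without contact between dorsal and
ventral tissue tend to develop mirror-symmetric internal anatomy
(double-dorsal or double-ventral limbs), while normal limbs are
dorsoventrally asymmetric. Judging this by eye is unreliable: accessory
limbs are morphologically variable, and staining intensity differs from
section to section. This package implements a quantitative pipeline:

1. classify every pixel of a trichrome-stained transverse section into
   five tissue classes — background (1), cartilage (2), muscle (3), other
   connective tissue (4), epidermis (5) — with a classifier trained
   per sample from sparse scribble annotations;
2. place a dorsoventral mirror axis from two user-clicked end points, cut
   a window of fixed 400 µm width, flip one half onto the other, and score
   per-class and combined mirror symmetry;
3. compare groups of limbs to intact controls with Welch's *t*-test, and
   summarize outcome-count tables as induction rates.

Because the original section images are not deposited, the package also
contains a seeded synthetic section generator with a controllable
asymmetry parameter, so the whole pipeline is testable end to end.

## The symmetry score

For a window split into a dorsal half and a vertically flipped ventral
half, and for each class $c$, two binary masks $M_d^c$ and $M_v^c$ mark
the pixels of that class in each half. The score is

$$ S_c \;=\; \frac{|M_d^c \cap M_v^c|}{|M_d^c \cup M_v^c|}, $$

the number of positions where the class is present on *both* sides over
the number where it is present on *either* side — a Jaccard index of the
two masks. The combined score pools counts over classes,
$S = \sum_c |M_d^c \cap M_v^c| \,/\, \sum_c |M_d^c \cup M_v^c|$, and is
therefore a mediant of the per-class ratios: it always lies between their
minimum and maximum. A class absent from both halves has an undefined
score and does not enter the pool. A perfect mirror gives exactly 1 for
every present class.

The denominator deserves a note. Verbal definitions of "total pixels" can
be read either as pixels matching on *either* side (the union above) or
as the sum of the two mask sizes. We score with the union by default
because it is the only reading under which a perfect mirror scores
exactly 1; `scoreWindow(..., denominator = "sum")` provides the
sum-of-masks variant ($|M_d| + |M_v|$ in the denominator, Dice-like but
without the factor 2) for sensitivity checks.

Scoring operates on classified label images by default (`tol` is ignored
there). RGB-domain scoring with a per-channel color tolerance — a pixel
matches a class color when all three channels are within `tol` — is
provided as well, because exported class-colored images are a common
interchange format; with `tol = 0` on palette-exact renders the two
routes agree exactly.

## Axis placement and windowing

The mirror axis is derived from the user-clicked dorsal and ventral end
points of the section: the raster is rotated so the dorsoventral segment
is vertical (`rotationDeg = -atan2(\Delta col, \Delta row)`), and the
mirror line is the midpoint of the two rotated row coordinates. Label
rasters are rotated with nearest-neighbour interpolation so no invented
classes appear; RGB rasters use bilinear interpolation.

Numerical conventions, chosen once and fixed:

* pixel coordinates are 1-based (row, col) with the origin at the top
  left; rows increase ventrally;
* the mirror row is snapped to the half-integer grid so rows pair
  exactly; when the dorsoventral extent is odd, the centre row belongs to
  neither half, so the axis is never double-counted;
* window width in pixels is `round(width_um / scale)` forced even, so the
  two halves are equal and the mirror line falls between rows;
* the 400 µm default window width limits the influence of section
  curvature and fixation distortion on the score.

The manual step of tilting a section until its outer contour "looks
symmetric" is formalized by `refineAngle()`: a grid search over rotation
offsets that maximizes the epidermis-class (class 5) score inside the
window. Ties go to the smallest absolute offset, negative before
positive, so the search is deterministic. This is an interpretation of a
qualitative manual criterion, not a reconstruction of it; the default
pipeline leaves refinement off (`refineDeg = 0`).

## Per-sample pixel classification

Staining intensity varies between samples, so a region that is "muscle
red" in one section can match "connective pink" in another. The pipeline
therefore trains one classifier per sample (annotations may be pooled
across images of the same limb), exactly as an interactive
pixel-classification tool is used in practice.

Features per pixel and channel: the raw intensity, plus at each smoothing
scale $\sigma \in \{1, 2, 4\}$ px the Gaussian-smoothed intensity, the
gradient magnitude of the smoothed channel, and its Laplacian — the
standard color/edge/texture triad — giving $3(1 + 3 \cdot 3) = 30$
features. All filters use reflective boundary handling, so constant
images yield exactly constant smoothed features and exactly zero
derivatives.

The learner is a seeded bagged ensemble of 100 fully grown CART trees
(`cp = 0`, `minsplit = 2`), i.e. an ensemble of decision trees over the
feature vectors of exactly the annotated pixels. Two design details
matter and were chosen deliberately:

* **Raw color planes come first in the feature stack.** The split search
  scans features in order and keeps the first best split, so whenever raw
  color and a derived feature are equally informative on the training
  set, the tree splits on raw color. On a noiseless palette-colored
  render this makes the ensemble provably color-driven, and ground truth
  is recovered pixel-exactly.
* **Scribbles should be drawn uniformly over a tissue, edges included.**
  If annotations avoid region boundaries entirely, the smoothed and
  derivative features take only their interior values in the training
  set and can look spuriously discriminative (e.g. a near-zero gradient
  threshold that "separates" background); the classifier then
  misgeneralizes at every tissue boundary. `sampleAnnotations()` samples
  uniformly by default; `interiorMargin` exists to study the
  interior-only failure mode.

Prediction sums the per-tree class-probability votes; exact vote ties
resolve to the lowest class index, so classification is a pure,
deterministic function of model and features.

## The synthetic section generator

`generateLabelSection()` draws a limb-like cross-section: a smooth outer
contour (three low-order cosine radial harmonics, which makes the contour
exactly mirror-symmetric about the mid-row), an epidermis ring of fixed
thickness, a connective-tissue interior, and elliptical cartilage and
muscle elements. Elements are laid out on the dorsal half and mirrored
onto the ventral half by exact row reflection; a fraction `asymmetry` of
the ventral copies (rounded to a count) is instead re-drawn at
independent positions and orientations. Hence `asymmetry = 0` yields
rasters exactly invariant under reflection about the mid-row, and
`asymmetry = 1` has fully independent halves — an exact zero case plus a
graded knob. The contour itself is always symmetric so that external
shape never confounds internal-tissue symmetry. Elements that cannot fit
inside the contour raise an error rather than being silently truncated.

`renderStaining()` colors a label raster with per-class mean colors
scaled by one uniform per-sample intensity multiplier (default range
0.7–1.3, emulating section-to-section staining variation) plus
independent Gaussian channel noise (default sd 4), clipped to 0..255.
`makeCohort()` derives per-sample layout seeds, stain seeds and
multipliers from one master seed, so cohorts are exactly reproducible.

Defaults describe a 512 × 512 px canvas at 4 µm/px, so a 400 µm window
spans 100 columns. The test-suite and the acceptance script use 128–160
px canvases at the same scale with 1–3 elements per tissue, and cohorts
of 6 samples × 2 windows = 12 scored areas per group — how many limbs
contributed the 12 areas per group in the original design is not
recorded, so the generator exposes both knobs. These sizes are the
package's own choice of a compact but non-trivial fixture.

What the generator does *not* emulate: real trichrome texture within a
tissue, partial-volume color mixing at boundaries, curved or torn
sections, and spatially varying stain gradients. Passing tests therefore
demonstrate the correctness of the scoring machinery and the soundness of
the per-sample training workflow under controlled intensity variation —
not segmentation performance on real histology.

## Group statistics

`welchT()` implements the unequal-variance two-sample *t*-test with
Welch–Satterthwaite degrees of freedom, two-sided; `pairedT()` the paired
*t*-test. Both flag the zero-variance degenerate cases explicitly (equal
means give $t = 0, p = 1$; unequal means $p = 0$ with a degenerate flag)
instead of dividing by zero. `compareToIntact()` tests every group and
score column against the intact-limb reference — the intact limb serving
as the "typical asymmetric structure" — with *no* multiple-testing
correction by default, matching how per-class tests are conventionally
reported in this setting; `bh = TRUE` adds Benjamini–Hochberg adjusted
p-values. `fisher2x2()` supplements the rate table with a two-sided
Fisher exact test computed by hypergeometric summation.

Windows from the same limb are treated as independent observations, as in
the area-level testing convention this package mirrors; no mixed-effects
modelling of windows nested in limbs is attempted.

## A worked cohort

```{r cohort, eval = FALSE}
spec <- sectionSpec(heightPx = 160, widthPx = 160, nCartilage = 2,
                    nMuscle = 3, epidermisThicknessPx = 5)
cohort <- makeCohort(spec, c(intact_like = 0, regenerate_like = 0.8),
                     nPerGroup = 6, seed = 1)
scores <- scoreCohort(cohort, centers = c(70, 90))
compareToIntact(scores, "intact_like")
```

On this seeded cohort the full pipeline (render, per-sample training,
classification, scoring) separates the groups clearly; the acceptance
script (`scripts/acceptance.R`) recomputes the group means and the Welch
p-value from scratch at any seed.

## Known limitations

* The feature bank and classifier of the original interactive tool are
  not published; the defaults here are documented design decisions, not
  reconstructions, and any classifier meeting the package's invariants
  (exact recovery in the separable case, deterministic seeded training)
  is a conformant substitute.
* The pixel scale of a section is never inferred from the image; it is a
  required input (sidecar JSON or argument).
* Scores depend on the user-supplied dorsal/ventral end points; the
  package does not detect them automatically.
* The color tolerance used historically for RGB-domain scoring is not
  recorded; the default is 0 (palette-exact class images).
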