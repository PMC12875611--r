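# SectionSymmetry

Quantifies how mirror-symmetric the internal anatomy of a limb is in
transverse histological sections. It was built for a question from axolotl
limb regeneration: accessory limbs that form without contact between dorsal
and ventral tissue develop dorsoventrally *symmetric* internal structures
(double-dorsal / double-ventral limbs), whereas intact limbs are
asymmetric. The package turns that visual impression into numbers and
statistics, for biologists analysing trichrome-stained limb cross-sections
and for anyone needing a tested bilateral-symmetry score for label images.

The pipeline:

1. **Per-sample pixel classification.** Each RGB section is classified into
   five tissue classes — background (1), cartilage (2), muscle (3), other
   connective tissue (4), epidermis (5) — by a seeded bagged ensemble of
   100 decision trees trained on sparse scribble annotations of that sample
   (staining intensity varies between sections, so one classifier per
   sample). Features per pixel: raw color plus Gaussian-smoothed intensity,
   gradient magnitude and Laplacian at scales {1, 2, 4} px.
2. **Dorsoventral symmetry scoring.** The section is rotated so the
   user-clicked dorsal–ventral segment is vertical, a window of fixed
   400 µm width is cut, the ventral half is flipped onto the dorsal half,
   and each class *c* is scored as

   S_c = |M_d ∩ M_v| / |M_d ∪ M_v|,

   the pixels where class *c* is present on **both** sides over the pixels
   where it is present on **either** side (a per-class Jaccard index; 1 for
   a perfect mirror). The combined score pools counts over classes.
3. **Group statistics.** Welch's two-sided *t*-test of every group against
   the intact-limb reference, a paired *t*-test, a Fisher exact test, and
   outcome-count tables (regress / bump / limb) as induction-rate
   percentages.

Because the study's raw images are not deposited, the package includes a
seeded generator of limb-like synthetic sections with a tunable
dorsoventral asymmetry parameter, used throughout the tests to validate
the pipeline end to end.

## Worked example

```r
library(SectionSymmetry)

## a synthetic section with strongly asymmetric internal tissues
spec <- sectionSpec(heightPx = 160, widthPx = 160, nCartilage = 2,
                    nMuscle = 3, epidermisThicknessPx = 5,
                    asymmetry = 0.8, seed = 7)
lab <- generateLabelSection(spec)   # ground-truth labels
rgb <- renderStaining(lab, stainModel(), seed = 11)  # noisy stained render

## per-sample training from 25 scribble pixels per class, then classify
clf  <- trainPixelClassifier(extractFeatures(rgb),
                             sampleAnnotations(lab, 25, seed = 2), seed = 3)
pred <- classifyPixels(clf, extractFeatures(rgb))
pixelAccuracy(pred, lab)
#> [1] 0.981875

## symmetry of a 400 um window about the dorsoventral axis
ends <- sectionEndpoints(lab)
ax   <- placeAxis(pred, ends$dorsal, ends$ventral)
scoreWindow(extractWindow(pred, ax, windowSpec(80)))
#> SymmetryResult (denominator: union )
#>  sample window   class matching total     score  combined
#>  sample     w1 class_1     2289  2653 0.8627968 0.7094017
#>  sample     w1 class_2        0   185 0.0000000 0.7094017
#>  sample     w1 class_3      329  1324 0.2484894 0.7094017
#>  sample     w1 class_4     3436  4612 0.7450130 0.7094017
#>  sample     w1 class_5      586   586 1.0000000 0.7094017
```

The internal tissues (cartilage, class 2; muscle, class 3) score low —
their dorsal and ventral layouts were drawn largely independently — while
the epidermis ring (class 5), which the generator keeps symmetric, scores
exactly 1. The combined score 0.709 pools all matching/total counts. On an
`asymmetry = 0` section every defined score is exactly 1.0.

Induction-rate tables are summarized with exact fractions:

```r
r <- outcomeRates(table1Outcomes()); r[, 6:8] <- round(r[, 6:8], 1); r
#>   condition  N regress bump limb regress_pct bump_pct limb_pct
#>       AntBL  8       3    5    0        37.5     62.5      0.0
#>   AntBL + P  9       0    1    8         0.0     11.1     88.9
#>      PostBL  8       6    2    0        75.0     25.0      0.0
#>  PostBL + A  7       2    1    4        28.6     14.3     57.1
#>       DorBL 12       8    3    1        66.7     25.0      8.3
#>   DorBL + V 14       5    2    7        35.7     14.3     50.0
#>      VentBL 22      15    7    0        68.2     31.8      0.0
#>  VentBL + D 11       2    2    7        18.2     18.2     63.6
```

A command-line wrapper over the same functions ships at
`inst/scripts/section-symmetry.R` with subcommands `generate`, `train`,
`classify`, `score`, `compare` and `outcomes`; every run writes a JSON
manifest recording its parameters and seeds.

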