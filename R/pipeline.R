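#' @include synthetic.R classifier.R symmetry.R stats.R
NULL

#' Run the full symmetry pipeline over a synthetic cohort
#'
#' For every cohort sample: extract features from the stained render, draw
#' scribble annotations from the ground-truth labels (emulating the
#' per-sample manual annotation step), train that sample's classifier,
#' classify every pixel, place the dorsoventral axis on the user-clicked
#' end points, and score the requested windows. With
#' `useGroundTruth = TRUE` the classification stage is skipped and the
#' ground-truth labels are scored directly.
#'
#' @param cohort a cohort list from [makeCohort()].
#' @param centers numeric centre columns of the scoring windows.
#' @param widthUm window width in micrometres (default 400).
#' @param nPerClass scribble pixels per class for training.
#' @param useGroundTruth score the ground-truth labels instead of the
#'   classified render.
#' @param refineDeg if > 0, refine the axis angle against the epidermal
#'   contour within `[-refineDeg, refineDeg]` (0.5 degree steps).
#' @param palette the shared [ClassPalette-class].
#' @return a tidy score table (see [scoreTable()]), one row per sample and
#'   window.
#' @export
scoreCohort <- function(cohort, centers, widthUm = 400, nPerClass = 25L,
                        useGroundTruth = FALSE, refineDeg = 0,
                        palette = defaultPalette()) {
  rows <- lapply(cohort, function(s) {
    target <- if (useGroundTruth) s$labels
              else {
                fs <- extractFeatures(s$rgb)
                ann <- sampleAnnotations(s$labels, nPerClass,
                                         seed = s$layoutSeed %% 100000L,
                                         imageId = s$sampleId)
                clf <- trainPixelClassifier(fs, ann,
                                            seed = s$stainSeed %% 100000L)
                classifyPixels(clf, fs, palette)
              }
    ends <- sectionEndpoints(s$labels)
    axis <- placeAxis(target, ends$dorsal, ends$ventral)
    windows <- lapply(centers, windowSpec, widthUm = widthUm)
    if (refineDeg > 0)
      axis <- refineAngle(if (useGroundTruth) s$labels else target, axis,
                          windows[[1L]], searchDeg = refineDeg,
                          palette = palette)
    res <- scoreSample(target, axis, windows, palette = palette,
                       sampleId = s$sampleId)
    scoreTable(res, group = s$group)
  })
  do.call(rbind, rows)
}

#' Per-sample versus shared-classifier accuracy
#'
#' The experiment behind the per-sample training workflow: staining
#' intensity varies between samples, so a classifier trained on one
#' sample's annotations transfers poorly to another. Each sample is
#' classified once with its own classifier and once with the classifier of
#' the first cohort sample.
#'
#' @param cohort a cohort list from [makeCohort()] (length >= 2).
#' @param nPerClass scribble pixels per class.
#' @param palette the shared [ClassPalette-class].
#' @return data.frame with per-sample accuracy of the own and the shared
#'   (cross-sample) classifier.
#' @export
perSampleVsShared <- function(cohort, nPerClass = 25L,
                              palette = defaultPalette()) {
  stopifnot(length(cohort) >= 2L)
  feats <- lapply(cohort, function(s) extractFeatures(s$rgb))
  clfs <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    ann <- sampleAnnotations(s$labels, nPerClass,
                             seed = s$layoutSeed %% 100000L)
    trainPixelClassifier(feats[[i]], ann, seed = s$stainSeed %% 100000L)
  })
  do.call(rbind, lapply(seq_along(cohort), function(i) {
    own <- pixelAccuracy(classifyPixels(clfs[[i]], feats[[i]], palette),
                         cohort[[i]]$labels)
    shared <- pixelAccuracy(classifyPixels(clfs[[1L]], feats[[i]], palette),
                            cohort[[i]]$labels)
    data.frame(sample = cohort[[i]]$sampleId,
               multiplier = cohort[[i]]$multiplier,
               own = own, shared = shared, stringsAsFactors = FALSE)
  }))
}
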