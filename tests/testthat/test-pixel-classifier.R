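# small separable fixture: five horizontal bands, one per class
bandedLabels <- function(H = 50, W = 30) {
  labelImage(matrix(rep(1:5, each = H / 5 * W), H, W, byrow = TRUE),
             scaleUmPerPx = 4)
}

test_that("training validates the annotation contract", {
  lab <- bandedLabels()
  fs <- extractFeatures(renderStaining(lab, stainModel(noiseSd = 0),
                                       multiplier = 1), scales = 1)
  oneClass <- annotationSet(c(2, 3), c(2, 3), c(1, 1))
  expect_error(trainPixelClassifier(fs, oneClass), "at least 2 distinct")
  some <- annotationSet(c(2, 3), c(2, 3), c(1, 2))
  expect_error(trainPixelClassifier(fs, some, classes = 1:5),
               "zero annotations")
  expect_error(annotationSet(1, 1, 7), "1..5")
  expect_error(trainPixelClassifier(fs, annotationSet(999, 1, c(1))),
               "at least 2 distinct")
})

test_that("a separable banded image is learned from one scribble per class", {
  lab <- bandedLabels()
  img <- renderStaining(lab, stainModel(noiseSd = 0), multiplier = 1)
  fs <- extractFeatures(img, scales = 1)
  ann <- annotationSet(row = c(5, 15, 25, 35, 45), col = rep(15, 5),
                       class = 1:5)
  clf <- trainPixelClassifier(fs, ann, seed = 1)
  expect_identical(unname(clf@annotationCounts), rep(1L, 5))
  pred <- classifyPixels(clf, fs)
  # resubstitution on the annotated pixels is perfect
  expect_identical(labels(pred)[cbind(ann$row, ann$col)], ann$class)
})

test_that("training and prediction are deterministic given the seed", {
  lab <- bandedLabels()
  img <- renderStaining(lab, stainModel(noiseSd = 6), seed = 4,
                        multiplier = 1)
  fs <- extractFeatures(img, scales = c(1, 2))
  ann <- sampleAnnotations(lab, 10, seed = 2)
  p1 <- classifyPixels(trainPixelClassifier(fs, ann, seed = 9), fs)
  p2 <- classifyPixels(trainPixelClassifier(fs, ann, seed = 9), fs)
  expect_identical(labels(p1), labels(p2))
  # prediction is a pure function: repeated calls agree
  clf <- trainPixelClassifier(fs, ann, seed = 9)
  expect_identical(labels(classifyPixels(clf, fs)),
                   labels(classifyPixels(clf, fs)))
})

test_that("zero-noise palette renders are recovered exactly", {
  lab <- generateLabelSection(testSpec(seed = 12))
  img <- renderStaining(lab, stainModel(noiseSd = 0), multiplier = 1)
  fs <- extractFeatures(img)
  clf <- trainPixelClassifier(fs, sampleAnnotations(lab, 25, seed = 3),
                              seed = 4)
  expect_identical(labels(classifyPixels(clf, fs)), labels(lab))
})

test_that("feature layout mismatches are rejected", {
  lab <- bandedLabels()
  img <- renderStaining(lab, stainModel(noiseSd = 0), multiplier = 1)
  fs1 <- extractFeatures(img, scales = 1)
  fs2 <- extractFeatures(img, scales = c(1, 2))
  clf <- trainPixelClassifier(fs1, sampleAnnotations(lab, 5, seed = 1))
  expect_error(classifyPixels(clf, fs2), "feature layout")
})

test_that("classifiers serialize with a version header and round-trip", {
  lab <- bandedLabels()
  img <- renderStaining(lab, stainModel(noiseSd = 3), seed = 2,
                        multiplier = 1)
  fs <- extractFeatures(img, scales = 1)
  clf <- trainPixelClassifier(fs, sampleAnnotations(lab, 8, seed = 1),
                              seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  writePixelClassifier(clf, path)
  back <- readPixelClassifier(path)
  expect_identical(labels(classifyPixels(back, fs)),
                   labels(classifyPixels(clf, fs)))

  stale <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), stale)
  expect_error(readPixelClassifier(stale), "version-1")
})
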