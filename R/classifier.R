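#' @include AllClasses.R features.R io.R
NULL

#' Build an annotation table
#'
#' Sparse scribble annotations: one row per annotated pixel. This is the
#' training input of the per-sample pixel classifier.
#'
#' @param row,col 1-based pixel coordinates.
#' @param class class index of each annotated pixel (1..5).
#' @param imageId identifier of the annotated image.
#' @return data.frame with columns `row`, `col`, `class` and an `imageId`
#'   attribute.
#' @export
annotationSet <- function(row, col, class, imageId = "sample") {
  stopifnot(length(row) == length(col), length(row) == length(class))
  if (!all(class %in% 1:5))
    stop("annotation classes must lie in 1..5", call. = FALSE)
  ann <- data.frame(row = as.integer(row), col = as.integer(col),
                    class = as.integer(class))
  attr(ann, "imageId") <- imageId
  ann
}

## Chebyshev erosion: pixels of the mask whose full (2k+1) square
## neighbourhood stays inside the mask
erodeMask <- function(mask, k) {
  if (k < 1L) return(mask)
  ones <- rep(1, 2L * k + 1L)
  counts <- convolveSeparable(mask * 1, ones, ones)
  mask & counts > (2 * k + 1)^2 - 0.5
}

#' Sample scribble annotations from a ground-truth label image
#'
#' Emulates a user scribbling on each tissue: draws up to `nPerClass`
#' random pixels of every class present in the label raster, uniformly
#' over the class region. Uniform sampling matters: strokes that touch
#' region edges expose the classifier to the boundary values of the
#' smoothed and derivative features, without which those features look
#' spuriously discriminative on the training set and generalize poorly at
#' tissue boundaries. Set `interiorMargin > 0` to emulate a user who only
#' scribbles deep inside each tissue (per class the margin shrinks until
#' annotatable pixels remain, e.g. for the thin epidermis ring).
#'
#' @param x a [LabelImage-class] (ground truth).
#' @param nPerClass annotated pixels per class.
#' @param seed integer seed.
#' @param interiorMargin minimum distance (Chebyshev, pixels) from any
#'   class boundary; default 0 (uniform over the class).
#' @param imageId identifier recorded in the annotation table.
#' @return annotation data.frame (see [annotationSet()]).
#' @export
sampleAnnotations <- function(x, nPerClass = 25L, seed = 1L,
                              interiorMargin = 0L, imageId = "sample") {
  stopifnot(is(x, "LabelImage"))
  lab <- x@labels
  withr::with_seed(as.integer(seed), {
    parts <- lapply(sort(unique(as.vector(lab))), function(cl) {
      mask <- lab == cl
      k <- min(as.integer(interiorMargin),
               min(dim(lab)) %/% 2L - 1L)
      while (k > 0L) {
        er <- erodeMask(mask, k)
        if (any(er)) break
        k <- k - 1L
      }
      idx <- which(if (k > 0L) erodeMask(mask, k) else mask)
      idx <- idx[sample.int(length(idx), min(nPerClass, length(idx)))]
      data.frame(row = (idx - 1L) %% nrow(lab) + 1L,
                 col = (idx - 1L) %/% nrow(lab) + 1L,
                 class = cl)
    })
    ann <- do.call(rbind, parts)
    attr(ann, "imageId") <- imageId
    ann
  })
}

#' Read / write annotations as CSV
#'
#' @param path CSV file with columns `row`, `col`, `class`.
#' @return `readAnnotations` returns the annotation data.frame.
#' @export
readAnnotations <- function(path) {
  ann <- utils::read.csv(path)
  annotationSet(ann$row, ann$col, ann$class,
                imageId = if (!is.null(ann$image[1L])) ann$image[1L]
                          else "sample")
}

#' @rdname readAnnotations
#' @param ann annotation data.frame.
#' @export
writeAnnotations <- function(ann, path) {
  utils::write.csv(ann[, c("row", "col", "class")], path, row.names = FALSE)
  invisible(path)
}

annotationFeatureMatrix <- function(features, ann) {
  d <- dim(features@values)
  if (any(ann$row < 1L | ann$row > d[1L] | ann$col < 1L | ann$col > d[2L]))
    stop("annotation coordinates fall outside the image", call. = FALSE)
  X <- vapply(seq_len(d[3L]), function(f) {
    features@values[cbind(ann$row, ann$col, f)]
  }, numeric(nrow(ann)))
  X <- matrix(X, nrow = nrow(ann), ncol = d[3L])
  colnames(X) <- features@featureNames
  X
}

#' Train a per-sample pixel classifier
#'
#' Fits a seeded bagged ensemble of fully grown classification trees
#' (CART; 100 trees by default, each on a bootstrap resample) on exactly
#' the annotated pixels' feature vectors. Split search scans features in
#' their stack order, so equal-gain splits resolve deterministically to the
#' earliest feature — the raw color channels come first, which makes the
#' ensemble recover a noiseless palette render exactly. One classifier is
#' trained per sample by default because staining intensity varies from
#' section to section; annotations may be shared across images obtained
#' from the same limb by pooling their annotation tables before training.
#'
#' @param features a [FeatureStack-class] of the annotated image.
#' @param ann annotation data.frame (see [annotationSet()]).
#' @param seed integer training seed.
#' @param numTrees number of trees (default 100).
#' @param classes the declared class set; every declared class must carry at
#'   least one annotated pixel. Defaults to the classes present in `ann`.
#' @return a [PixelClassifier-class].
#' @export
trainPixelClassifier <- function(features, ann, seed = 1L, numTrees = 100L,
                                 classes = sort(unique(ann$class))) {
  stopifnot(is(features, "FeatureStack"))
  classes <- sort(as.integer(classes))
  counts <- table(factor(ann$class, levels = classes))
  if (any(counts == 0L))
    stop("declared class(es) with zero annotations: ",
         paste(classes[counts == 0L], collapse = ", "), call. = FALSE)
  if (length(classes) < 2L)
    stop("at least 2 distinct annotated classes are required", call. = FALSE)
  if (!all(ann$class %in% classes))
    stop("annotations contain classes outside the declared set",
         call. = FALSE)
  X <- as.data.frame(annotationFeatureMatrix(features, ann))
  colnames(X) <- make.names(features@featureNames)
  X$.class <- factor(ann$class, levels = classes)
  n <- nrow(X)
  trees <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(numTrees), function(i) {
      ## resample until the bootstrap carries at least 2 classes, so every
      ## tree can split; empty levels are dropped per tree and vote columns
      ## re-aligned at prediction time
      repeat {
        boot <- sample.int(n, replace = TRUE)
        if (nlevels(droplevels(X$.class[boot])) >= 2L) break
      }
      d <- X[boot, , drop = FALSE]
      d$.class <- droplevels(d$.class)
      rpart::rpart(.class ~ ., d, method = "class",
                   control = rpart::rpart.control(cp = 0, minsplit = 2L,
                                                  minbucket = 1L, xval = 0L))
    })
  })
  new("PixelClassifier", model = trees, classes = classes,
      featureNames = features@featureNames, scales = features@scales,
      annotationCounts = structure(as.integer(counts),
                                   names = as.character(classes)),
      seed = as.integer(seed))
}

#' Classify every pixel of a feature stack
#'
#' Assigns each pixel the class with the highest summed tree vote; exact
#' vote ties are broken toward the lowest class index. Prediction is a
#' pure function of the model and the features.
#'
#' @param clf a [PixelClassifier-class].
#' @param features a [FeatureStack-class] with the same feature layout the
#'   classifier was trained on.
#' @param palette the [ClassPalette-class] to attach to the result.
#' @return a [LabelImage-class] of predicted classes.
#' @export
classifyPixels <- function(clf, features, palette = defaultPalette()) {
  stopifnot(is(clf, "PixelClassifier"), is(features, "FeatureStack"))
  if (!identical(clf@featureNames, features@featureNames))
    stop("feature layout does not match the classifier's training layout",
         call. = FALSE)
  d <- dim(features@values)
  X <- as.data.frame(matrix(features@values, nrow = d[1L] * d[2L],
                            ncol = d[3L]))
  colnames(X) <- make.names(features@featureNames)
  classNames <- as.character(clf@classes)
  votes <- matrix(0, nrow(X), length(classNames),
                  dimnames = list(NULL, classNames))
  for (tr in clf@model) {
    p <- predict(tr, X, type = "prob")
    votes[, colnames(p)] <- votes[, colnames(p), drop = FALSE] + p
  }
  ## vote columns are in ascending class order, so ties.method = "first"
  ## resolves ties to the lowest class
  cls <- clf@classes[max.col(votes, ties.method = "first")]
  labelImage(matrix(cls, d[1L], d[2L]), palette, features@scaleUmPerPx)
}

#' Per-pixel agreement between two label images
#'
#' @param pred,truth two [LabelImage-class] objects of identical size.
#' @return fraction of pixels with identical class.
#' @export
pixelAccuracy <- function(pred, truth) {
  stopifnot(identical(dim(pred@labels), dim(truth@labels)))
  mean(pred@labels == truth@labels)
}

#' Serialize / restore a trained classifier
#'
#' The file carries a format-version header so stale models are rejected
#' on load.
#'
#' @param clf a [PixelClassifier-class].
#' @param path output file path.
#' @return `readPixelClassifier` returns the restored classifier.
#' @export
writePixelClassifier <- function(clf, path) {
  saveRDS(list(format = "SectionSymmetry.PixelClassifier", version = 1L,
               classifier = clf), path)
  invisible(path)
}

#' @rdname writePixelClassifier
#' @export
readPixelClassifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "SectionSymmetry.PixelClassifier") ||
      !identical(obj$version, 1L))
    stop("not a version-1 classifier file: ", path, call. = FALSE)
  obj$classifier
}
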