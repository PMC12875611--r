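#' @include AllClasses.R
NULL

#' Accessors for raster objects
#'
#' @param x an object of one of the package's raster classes.
#' @return `pixels` returns the H x W x 3 integer array of an
#'   [RGBImage-class]; `labels` the integer label matrix of a
#'   [LabelImage-class]; `classPalette` the attached [ClassPalette-class];
#'   `scaleUmPerPx` the physical scale in micrometres per pixel.
#' @name raster-accessors
#' @aliases pixels labels classPalette scaleUmPerPx
#' @examples
#' img <- generateLabelSection(sectionSpec(heightPx = 64, widthPx = 64))
#' dim(labels(img))
#' scaleUmPerPx(img)
NULL

#' @rdname raster-accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname raster-accessors
#' @export
setGeneric("labels")

#' @rdname raster-accessors
#' @export
setGeneric("classPalette", function(x) standardGeneric("classPalette"))

#' @rdname raster-accessors
#' @export
setGeneric("scaleUmPerPx", function(x) standardGeneric("scaleUmPerPx"))

#' @rdname raster-accessors
setMethod("pixels", "RGBImage", function(x) x@pixels)

#' @rdname raster-accessors
setMethod("labels", "LabelImage", function(object, ...) object@labels)

#' @rdname raster-accessors
setMethod("classPalette", "LabelImage", function(x) x@palette)

#' @rdname raster-accessors
setMethod("scaleUmPerPx", "RGBImage", function(x) x@scaleUmPerPx)

#' @rdname raster-accessors
setMethod("scaleUmPerPx", "LabelImage", function(x) x@scaleUmPerPx)

#' @rdname raster-accessors
setMethod("scaleUmPerPx", "FeatureStack", function(x) x@scaleUmPerPx)

setMethod("show", "ClassPalette", function(object) {
  cat("ClassPalette with", length(object@classIndex), "classes\n")
  for (i in seq_along(object@classIndex)) {
    cat(sprintf("  %d: %-24s rgb(%s)\n", object@classIndex[i],
                object@className[i],
                paste(object@colors[i, ], collapse = ", ")))
  }
})

setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBImage %d x %d px, %.3g um/px\n", d[1L], d[2L],
              object@scaleUmPerPx))
})

setMethod("show", "LabelImage", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels, levels = object@palette@classIndex))
  cat(sprintf("LabelImage %d x %d px, %.3g um/px\n", d[1L], d[2L],
              object@scaleUmPerPx))
  cat("  class counts:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = " "), "\n")
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureStack %d x %d px, %d features (scales: %s px)\n",
              d[1L], d[2L], d[3L],
              paste(object@scales, collapse = ", ")))
})

setMethod("show", "PixelClassifier", function(object) {
  cat("PixelClassifier (random forest,",
      object@model$num.trees, "trees)\n")
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
  cat("  annotations per class:",
      paste(sprintf("%s=%d", names(object@annotationCounts),
                    object@annotationCounts), collapse = " "), "\n")
})

setMethod("show", "AxisSpec", function(object) {
  cat(sprintf(
    "AxisSpec dorsal (%g, %g) -> ventral (%g, %g): rotation %.3f deg, mirror row %.1f\n",
    object@dorsalPoint[1L], object@dorsalPoint[2L],
    object@ventralPoint[1L], object@ventralPoint[2L],
    object@rotationDeg, object@mirrorRow))
})

setMethod("show", "SymmetryWindow", function(object) {
  d <- dim(object@dorsal)
  cat(sprintf("SymmetryWindow: two %s halves of %d x %d px (%s)\n",
              if (object@isLabel) "label" else "RGB", d[1L], d[2L],
              object@sampleId))
})

setMethod("show", "SymmetryResult", function(object) {
  cat("SymmetryResult (denominator:", object@denominator, ")\n")
  df <- as.data.frame(object)
  print(df, row.names = FALSE)
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, df = %.3g, p = %.4g (n = %d, %d)%s\n",
              object@method, object@statistic, object@df, object@pValue,
              object@nA, object@nB,
              if (object@degenerate) " [degenerate variance]" else ""))
})

#' @export
as.data.frame.SymmetryResult <- function(x, ...) {
  data.frame(
    sample = x@sampleId, window = x@windowId,
    class = names(x@total),
    matching = unname(x@matching), total = unname(x@total),
    score = unname(x@score), combined = x@combined,
    stringsAsFactors = FALSE
  )
}

#' @export
as.data.frame.TestResult <- function(x, ...) {
  data.frame(method = x@method, statistic = x@statistic, df = x@df,
             p = x@pValue, n_a = x@nA, n_b = x@nB,
             degenerate = x@degenerate, stringsAsFactors = FALSE)
}
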