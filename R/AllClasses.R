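#' @import methods
NULL

#' Five-class tissue palette
#'
#' Ordered mapping between tissue class indices 1..5, class names, and the
#' display colors used in rendered label images. The fixed scheme is
#' class 1 = background, 2 = cartilage, 3 = muscle, 4 = other connective
#' tissue, 5 = epidermis.
#'
#' @slot classIndex integer vector of class indices (1..5, no repeats).
#' @slot className character vector of class names.
#' @slot colors integer matrix (5 x 3) of RGB display colors, 0..255,
#'   pairwise distinct rows.
#' @slot backgroundIndex index of the background class (default 1).
#' @exportClass ClassPalette
setClass("ClassPalette",
  representation(
    classIndex = "integer",
    className = "character",
    colors = "matrix",
    backgroundIndex = "integer"
  )
)

setValidity("ClassPalette", function(object) {
  msg <- character(0)
  n <- length(object@classIndex)
  if (n != 5L) msg <- c(msg, "palette must have exactly 5 entries")
  if (anyDuplicated(object@classIndex) || !setequal(object@classIndex, 1:5))
    msg <- c(msg, "class indices must be 1..5 with no repeats")
  if (length(object@className) != n)
    msg <- c(msg, "one name per class required")
  if (!is.numeric(object@colors) || !identical(dim(object@colors), c(5L, 3L)))
    msg <- c(msg, "colors must be a 5 x 3 matrix")
  else {
    if (any(object@colors < 0 | object@colors > 255))
      msg <- c(msg, "colors must lie in 0..255")
    if (anyDuplicated(apply(object@colors, 1L, paste, collapse = ",")))
      msg <- c(msg, "palette colors must be pairwise distinct")
  }
  if (!(object@backgroundIndex %in% object@classIndex))
    msg <- c(msg, "backgroundIndex must be a declared class index")
  if (length(msg)) msg else TRUE
})

#' RGB section image
#'
#' An 8-bit 3-channel raster with a physical scale. Pixel coordinates are
#' 1-based (row, col) with the origin at the top-left corner; rows increase
#' ventrally (the top of the image is dorsal).
#'
#' @slot pixels integer array (H x W x 3), values 0..255.
#' @slot scaleUmPerPx physical scale in micrometres per pixel (> 0).
#' @exportClass RGBImage
setClass("RGBImage",
  representation(pixels = "array", scaleUmPerPx = "numeric")
)

setValidity("RGBImage", function(object) {
  d <- dim(object@pixels)
  msg <- character(0)
  if (length(d) != 3L || d[3L] != 3L)
    msg <- c(msg, "pixels must be an H x W x 3 array")
  else if (d[1L] < 1L || d[2L] < 1L)
    msg <- c(msg, "image must have at least one row and one column")
  if (any(object@pixels < 0 | object@pixels > 255))
    msg <- c(msg, "pixel values must lie in 0..255")
  if (length(object@scaleUmPerPx) != 1L || !is.finite(object@scaleUmPerPx) ||
      object@scaleUmPerPx <= 0)
    msg <- c(msg, "scaleUmPerPx must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Class-label raster
#'
#' A per-pixel tissue classification tied to a [ClassPalette-class].
#'
#' @slot labels integer matrix (H x W); every value is a declared class index.
#' @slot palette the [ClassPalette-class] the labels refer to.
#' @slot scaleUmPerPx micrometres per pixel (> 0).
#' @exportClass LabelImage
setClass("LabelImage",
  representation(
    labels = "matrix",
    palette = "ClassPalette",
    scaleUmPerPx = "numeric"
  )
)

setValidity("LabelImage", function(object) {
  msg <- character(0)
  if (!all(object@labels %in% object@palette@classIndex))
    msg <- c(msg, "every label must be a declared palette class index")
  if (length(object@scaleUmPerPx) != 1L || object@scaleUmPerPx <= 0)
    msg <- c(msg, "scaleUmPerPx must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Synthetic section layout parameters
#'
#' Controls the seeded generator of limb-like cross-sections: canvas size and
#' scale, tissue element counts, epidermis ring thickness, and the
#' dorsoventral asymmetry knob (0 = internal tissues exactly mirror the
#' dorsal half onto the ventral half; 1 = dorsal and ventral element layouts
#' are drawn independently).
#'
#' @slot heightPx,widthPx canvas size in pixels.
#' @slot scaleUmPerPx micrometres per pixel.
#' @slot nCartilage,nMuscle numbers of cartilage / muscle elements per half.
#' @slot epidermisThicknessPx thickness of the epidermis ring in pixels.
#' @slot asymmetry real in [0, 1]; fraction of ventral element placements
#'   re-drawn independently instead of mirrored.
#' @slot seed integer seed controlling the layout.
#' @exportClass SectionSpec
setClass("SectionSpec",
  representation(
    heightPx = "integer", widthPx = "integer",
    scaleUmPerPx = "numeric",
    nCartilage = "integer", nMuscle = "integer",
    epidermisThicknessPx = "integer",
    asymmetry = "numeric", seed = "integer"
  )
)

setValidity("SectionSpec", function(object) {
  msg <- character(0)
  if (object@heightPx < 16L || object@widthPx < 16L)
    msg <- c(msg, "canvas must be at least 16 x 16 pixels")
  if (object@scaleUmPerPx <= 0)
    msg <- c(msg, "scaleUmPerPx must be positive")
  if (object@nCartilage < 0L || object@nMuscle < 0L)
    msg <- c(msg, "element counts must be non-negative")
  if (object@epidermisThicknessPx < 1L)
    msg <- c(msg, "epidermis thickness must be at least 1 pixel")
  if (object@asymmetry < 0 || object@asymmetry > 1)
    msg <- c(msg, "asymmetry must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Trichrome-like stain rendering model
#'
#' Per-class mean colors, a per-sample global intensity multiplier range, and
#' additive per-pixel Gaussian noise. Emulates the sample-to-sample staining
#' intensity variation of real trichrome sections that motivates training one
#' pixel classifier per sample.
#'
#' @slot meanColors numeric matrix (5 x 3), mean RGB per class, pairwise
#'   distinct rows.
#' @slot multRange length-2 numeric (lo, hi) from which one intensity
#'   multiplier per sample is drawn uniformly.
#' @slot noiseSd standard deviation of the additive per-channel noise (>= 0).
#' @exportClass StainModel
setClass("StainModel",
  representation(meanColors = "matrix", multRange = "numeric",
                 noiseSd = "numeric")
)

setValidity("StainModel", function(object) {
  msg <- character(0)
  if (!identical(dim(object@meanColors), c(5L, 3L)))
    msg <- c(msg, "meanColors must be a 5 x 3 matrix")
  else if (anyDuplicated(apply(object@meanColors, 1L, paste, collapse = ",")))
    msg <- c(msg, "mean colors must be pairwise distinct")
  if (length(object@multRange) != 2L || object@multRange[1L] > object@multRange[2L])
    msg <- c(msg, "multRange must be (lo, hi) with lo <= hi")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-pixel feature stack
#'
#' Multi-scale features for pixel classification: per channel the raw
#' intensity plus, at each smoothing scale, the Gaussian-smoothed intensity,
#' the gradient magnitude of the smoothed channel, and its Laplacian.
#'
#' @slot values numeric array (H x W x F), finite.
#' @slot featureNames ordered feature names (length F).
#' @slot scales smoothing scales used, in pixels.
#' @slot scaleUmPerPx physical scale carried from the source image.
#' @exportClass FeatureStack
setClass("FeatureStack",
  representation(values = "array", featureNames = "character",
                 scales = "numeric", scaleUmPerPx = "numeric")
)

setValidity("FeatureStack", function(object) {
  d <- dim(object@values)
  msg <- character(0)
  if (length(d) != 3L) msg <- c(msg, "values must be an H x W x F array")
  else if (d[3L] != length(object@featureNames))
    msg <- c(msg, "one name per feature plane required")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "feature values must be finite")
  if (length(msg)) msg else TRUE
})

#' Trained per-sample pixel classifier
#'
#' A seeded random-forest (ensemble of decision trees) classifier over
#' feature vectors, with the training metadata needed to validate that
#' prediction-time features match the training layout.
#'
#' @slot model the fitted ranger probability forest.
#' @slot classes integer vector of trained class indices (sorted).
#' @slot featureNames feature layout the model was trained on.
#' @slot scales smoothing scales of the training features.
#' @slot annotationCounts named integer vector, annotated pixels per class.
#' @slot seed integer seed used for training.
#' @exportClass PixelClassifier
setClass("PixelClassifier",
  representation(model = "ANY", classes = "integer",
                 featureNames = "character", scales = "numeric",
                 annotationCounts = "integer", seed = "integer")
)

#' Dorsoventral symmetry axis
#'
#' Placement of the mirror axis: the user-supplied dorsal and ventral end
#' points, the rotation (degrees) that brings the dorsoventral segment to
#' vertical, and the mirror row (midpoint of the rotated end points, a real
#' row coordinate perpendicular to the rotated segment).
#'
#' @slot dorsalPoint,ventralPoint (row, col) pixel coordinates, 1-based.
#' @slot rotationDeg rotation in degrees applied to the raster before
#'   mirroring.
#' @slot mirrorRow real row coordinate of the mirror line after rotation.
#' @slot centerCol column of the rotated dorsoventral segment.
#' @exportClass AxisSpec
setClass("AxisSpec",
  representation(dorsalPoint = "numeric", ventralPoint = "numeric",
                 rotationDeg = "numeric", mirrorRow = "numeric",
                 centerCol = "numeric")
)

#' Scoring window specification
#'
#' An axis-aligned window of fixed physical width (default 400 micrometres,
#' the width used to factor out section curvature) centred on a column of the
#' rotated raster. The pixel width is derived from the image scale and forced
#' even so the mirror line sits between rows, never on one.
#'
#' @slot centerCol centre column of the window in the rotated raster.
#' @slot widthUm physical window width in micrometres (> 0).
#' @exportClass WindowSpec
setClass("WindowSpec",
  representation(centerCol = "numeric", widthUm = "numeric")
)

setValidity("WindowSpec", function(object) {
  if (object@widthUm <= 0) "widthUm must be positive" else TRUE
})

#' Mirror-aligned window halves
#'
#' The dorsal half and the vertically flipped ventral half of a scoring
#' window, cropped to equal shape so that position (i, j) in one half is the
#' mirror partner of (i, j) in the other.
#'
#' @slot dorsal,ventral equal-shaped rasters (label matrix or RGB array);
#'   the ventral half is stored already flipped about the mirror line.
#' @slot isLabel TRUE for label rasters, FALSE for RGB.
#' @slot scaleUmPerPx micrometres per pixel.
#' @slot sampleId,windowId provenance tags.
#' @exportClass SymmetryWindow
setClass("SymmetryWindow",
  representation(dorsal = "ANY", ventral = "ANY", isLabel = "logical",
                 scaleUmPerPx = "numeric", sampleId = "character",
                 windowId = "character")
)

setValidity("SymmetryWindow", function(object) {
  dd <- dim(object@dorsal); dv <- dim(object@ventral)
  if (!identical(dd, dv)) return("halves must have identical dimensions")
  if (dd[1L] < 1L) return("halves must contain at least one row")
  TRUE
})

#' Symmetry scores for one window
#'
#' Per-class matching/total pixel counts and scores in [0, 1], plus the
#' combined score pooling counts over all classes. A class absent from both
#' halves has total 0 and an undefined (NA) score.
#'
#' @slot matching,total named numeric vectors of per-class pixel counts.
#' @slot score named numeric vector, matching/total (NA where total is 0).
#' @slot combined pooled score sum(matching)/sum(total).
#' @slot denominator "union" (pixels matching on either side; Jaccard) or
#'   "sum" (|dorsal mask| + |ventral mask|; Dice-like).
#' @slot sampleId,windowId provenance tags.
#' @exportClass SymmetryResult
setClass("SymmetryResult",
  representation(matching = "numeric", total = "numeric", score = "numeric",
                 combined = "numeric", denominator = "character",
                 sampleId = "character", windowId = "character")
)

setValidity("SymmetryResult", function(object) {
  msg <- character(0)
  if (any(object@matching > object@total))
    msg <- c(msg, "matching count cannot exceed total count")
  ok <- !is.na(object@score)
  if (any(object@score[ok] < 0 | object@score[ok] > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Two-sample test result
#'
#' @slot statistic test statistic.
#' @slot df degrees of freedom (NA for degenerate branches).
#' @slot pValue two-sided p-value in [0, 1].
#' @slot nA,nB per-group sample sizes.
#' @slot method test name.
#' @slot degenerate TRUE when both samples had zero variance and the p-value
#'   comes from the degenerate branch.
#' @exportClass TestResult
setClass("TestResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 nA = "integer", nB = "integer", method = "character",
                 degenerate = "logical")
)

setValidity("TestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) "p-value must lie in [0, 1]"
  else TRUE
})
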