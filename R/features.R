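#' @include AllClasses.R
NULL

## symmetric (half-sample) reflection indices for padding a length-n axis by k
reflectIndices <- function(n, k) {
  if (k >= n) stop("image too small for the requested filter scale",
                   call. = FALSE)
  c(k:1, 1:n, n:(n - k + 1L))
}

## separable 1-D convolution down the rows, then down the columns, with
## reflective boundary handling; kernel must have odd length
convolveSeparable <- function(mat, kernelRows, kernelCols) {
  k1 <- (length(kernelRows) - 1L) %/% 2L
  k2 <- (length(kernelCols) - 1L) %/% 2L
  x <- mat[reflectIndices(nrow(mat), k1), , drop = FALSE]
  x <- stats::filter(x, kernelRows, method = "convolution", sides = 2L)
  x <- x[(k1 + 1L):(k1 + nrow(mat)), , drop = FALSE]
  x <- t(x)[reflectIndices(ncol(mat), k2), , drop = FALSE]
  x <- stats::filter(x, kernelCols, method = "convolution", sides = 2L)
  t(x[(k2 + 1L):(k2 + ncol(mat)), , drop = FALSE])
}

gaussianKernel <- function(sigma) {
  k <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(seq(-k, k), sd = sigma)
  g / sum(g)
}

gaussianSmooth <- function(mat, sigma) {
  g <- gaussianKernel(sigma)
  convolveSeparable(mat, g, g)
}

## central-difference derivatives and Laplacian, reflective boundaries
derivRows <- function(mat) {
  x <- mat[reflectIndices(nrow(mat), 1L), , drop = FALSE]
  y <- stats::filter(x, c(-0.5, 0, 0.5), method = "convolution", sides = 2L)
  y[2:(nrow(mat) + 1L), , drop = FALSE]
}

derivCols <- function(mat) t(derivRows(t(mat)))

secondDerivRows <- function(mat) {
  x <- mat[reflectIndices(nrow(mat), 1L), , drop = FALSE]
  y <- stats::filter(x, c(1, -2, 1), method = "convolution", sides = 2L)
  y[2:(nrow(mat) + 1L), , drop = FALSE]
}

gradientMagnitude <- function(mat) {
  sqrt(derivRows(mat)^2 + derivCols(mat)^2)
}

laplacian <- function(mat) {
  secondDerivRows(mat) + t(secondDerivRows(t(mat)))
}

#' Extract a multi-scale feature stack for pixel classification
#'
#' The feature bank follows the standard "color + edge + texture" triad of
#' interactive pixel-classification tools: per channel the raw intensity
#' plus, at every smoothing scale, the Gaussian-smoothed intensity, the
#' gradient magnitude of the smoothed channel, and its Laplacian. All
#' filters use reflective boundary handling, so a constant image yields
#' constant smoothed features and exactly zero derivative features. With
#' `S` scales the stack holds `3 * (1 + 3 * S)` feature planes. The three
#' raw color planes come first in the stack: the classifier's split search
#' prefers earlier features on equal gain, so exact color evidence
#' dominates derived evidence whenever both are equally informative.
#'
#' @param img an [RGBImage-class].
#' @param scales positive smoothing scales in pixels (default 1, 2, 4).
#' @return a [FeatureStack-class].
#' @export
#' @examples
#' img <- rgbImage(array(128L, c(16, 16, 3)), scaleUmPerPx = 4)
#' extractFeatures(img, scales = 1)
extractFeatures <- function(img, scales = c(1, 2, 4)) {
  stopifnot(is(img, "RGBImage"))
  if (length(scales) < 1L || any(scales <= 0))
    stop("scales must be a non-empty list of positive values", call. = FALSE)
  d <- dim(img@pixels)
  nFeat <- 3L * (1L + 3L * length(scales))
  vals <- array(0, c(d[1L], d[2L], nFeat))
  nm <- character(nFeat)
  chNames <- c("R", "G", "B")
  f <- 0L
  for (ch in 1:3) {
    f <- f + 1L
    vals[, , f] <- img@pixels[, , ch]
    nm[f] <- paste0(chNames[ch], ".raw")
  }
  for (ch in 1:3) {
    x <- img@pixels[, , ch]
    for (s in scales) {
      sm <- gaussianSmooth(x, s)
      f <- f + 1L
      vals[, , f] <- sm
      nm[f] <- sprintf("%s.gauss.s%g", chNames[ch], s)
      f <- f + 1L
      vals[, , f] <- gradientMagnitude(sm)
      nm[f] <- sprintf("%s.gradmag.s%g", chNames[ch], s)
      f <- f + 1L
      vals[, , f] <- laplacian(sm)
      nm[f] <- sprintf("%s.laplace.s%g", chNames[ch], s)
    }
  }
  new("FeatureStack", values = vals, featureNames = nm,
      scales = as.numeric(scales), scaleUmPerPx = img@scaleUmPerPx)
}
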