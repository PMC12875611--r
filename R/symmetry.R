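#' @include AllClasses.R io.R
NULL

degToRad <- function(d) d * pi / 180

## plane rotation of (row, col) offsets by beta degrees:
## r' = r cos(b) - c sin(b); c' = r sin(b) + c cos(b)
rotatePoint <- function(p, betaDeg, center) {
  b <- degToRad(betaDeg)
  dr <- p[1L] - center[1L]; dc <- p[2L] - center[2L]
  c(center[1L] + dr * cos(b) - dc * sin(b),
    center[2L] + dr * sin(b) + dc * cos(b))
}

rasterCenter <- function(d) c((d[1L] + 1) / 2, (d[2L] + 1) / 2)

## nearest-neighbour remap (label rasters: no invented classes)
rotateMatrixNN <- function(mat, betaDeg, fill) {
  if (betaDeg == 0) return(mat)
  H <- nrow(mat); W <- ncol(mat)
  ctr <- rasterCenter(c(H, W))
  b <- degToRad(-betaDeg)
  qr <- matrix(seq_len(H), H, W) - ctr[1L]
  qc <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2L]
  sr <- round(ctr[1L] + qr * cos(b) - qc * sin(b))
  sc <- round(ctr[2L] + qr * sin(b) + qc * cos(b))
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  out <- matrix(fill, H, W)
  out[ok] <- mat[cbind(sr[ok], sc[ok])]
  out
}

## bilinear remap (RGB rasters)
rotateMatrixBilinear <- function(mat, betaDeg, fill) {
  if (betaDeg == 0) return(mat)
  H <- nrow(mat); W <- ncol(mat)
  ctr <- rasterCenter(c(H, W))
  b <- degToRad(-betaDeg)
  qr <- matrix(seq_len(H), H, W) - ctr[1L]
  qc <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2L]
  sr <- ctr[1L] + qr * cos(b) - qc * sin(b)
  sc <- ctr[2L] + qr * sin(b) + qc * cos(b)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
  out <- matrix(as.numeric(fill), H, W)
  g <- function(ri, ci) mat[cbind(ri, ci)]
  i0 <- r0[ok]; j0 <- c0[ok]; a <- fr[ok]; bb <- fc[ok]
  out[ok] <- (1 - a) * (1 - bb) * g(i0, j0) +
             (1 - a) * bb * g(i0, j0 + 1) +
             a * (1 - bb) * g(i0 + 1, j0) +
             a * bb * g(i0 + 1, j0 + 1)
  out
}

rotateRaster <- function(x, betaDeg) {
  if (is(x, "LabelImage")) {
    labelImage(rotateMatrixNN(x@labels, betaDeg,
                              fill = x@palette@backgroundIndex),
               x@palette, x@scaleUmPerPx)
  } else if (is(x, "RGBImage")) {
    d <- dim(x@pixels)
    arr <- array(0, d)
    for (ch in 1:3)
      arr[, , ch] <- rotateMatrixBilinear(x@pixels[, , ch], betaDeg,
                                          fill = 255)
    rgbImage(pmin(pmax(round(arr), 0), 255), x@scaleUmPerPx)
  } else stop("expected a LabelImage or RGBImage", call. = FALSE)
}

#' Place the dorsoventral symmetry axis
#'
#' The mirror axis is the perpendicular bisector of the segment joining the
#' user-supplied dorsal and ventral end points. The returned rotation (in
#' degrees) brings that segment to vertical with the dorsal point on top;
#' the mirror row is the midpoint of the two rotated row coordinates.
#'
#' @param x the section ([LabelImage-class] or [RGBImage-class]).
#' @param dorsalPoint,ventralPoint (row, col) 1-based pixel coordinates of
#'   the dorsal and ventral ends.
#' @return an [AxisSpec-class].
#' @export
#' @examples
#' img <- labelImage(matrix(1L, 100, 100), scaleUmPerPx = 4)
#' placeAxis(img, c(10, 50), c(90, 50))
placeAxis <- function(x, dorsalPoint, ventralPoint) {
  d <- if (is(x, "LabelImage")) dim(x@labels) else dim(x@pixels)[1:2]
  pts <- rbind(dorsalPoint, ventralPoint)
  if (any(pts[, 1L] < 1 | pts[, 1L] > d[1L] |
          pts[, 2L] < 1 | pts[, 2L] > d[2L]))
    stop("axis end points must lie inside the raster", call. = FALSE)
  if (all(dorsalPoint == ventralPoint))
    stop("dorsal and ventral points must differ", call. = FALSE)
  phi <- atan2(ventralPoint[2L] - dorsalPoint[2L],
               ventralPoint[1L] - dorsalPoint[1L])
  rot <- -phi * 180 / pi
  ctr <- rasterCenter(d)
  dp <- rotatePoint(dorsalPoint, rot, ctr)
  vp <- rotatePoint(ventralPoint, rot, ctr)
  new("AxisSpec", dorsalPoint = as.numeric(dorsalPoint),
      ventralPoint = as.numeric(ventralPoint),
      rotationDeg = rot, mirrorRow = (dp[1L] + vp[1L]) / 2,
      centerCol = (dp[2L] + vp[2L]) / 2)
}

## re-derive mirror row / center column for a modified rotation
axisWithRotation <- function(axis, rotationDeg, dims) {
  ctr <- rasterCenter(dims)
  dp <- rotatePoint(axis@dorsalPoint, rotationDeg, ctr)
  vp <- rotatePoint(axis@ventralPoint, rotationDeg, ctr)
  new("AxisSpec", dorsalPoint = axis@dorsalPoint,
      ventralPoint = axis@ventralPoint, rotationDeg = rotationDeg,
      mirrorRow = (dp[1L] + vp[1L]) / 2, centerCol = (dp[2L] + vp[2L]) / 2)
}

#' Specify a scoring window
#'
#' @param centerCol centre column of the window in the rotated raster.
#' @param widthUm physical window width in micrometres (default 400, the
#'   fixed width used to factor out section curvature).
#' @return a [WindowSpec-class].
#' @export
windowSpec <- function(centerCol, widthUm = 400) {
  new("WindowSpec", centerCol = as.numeric(centerCol),
      widthUm = as.numeric(widthUm))
}

#' Window width in pixels
#'
#' `round(widthUm / scale)` forced to the nearest even integer, so that the
#' mirror line sits between rows and the two halves have equal width.
#'
#' @param window a [WindowSpec-class].
#' @param scaleUmPerPx micrometres per pixel.
#' @return even integer pixel width (>= 2).
#' @export
windowWidthPx <- function(window, scaleUmPerPx) {
  max(2L, 2L * as.integer(round(window@widthUm / scaleUmPerPx / 2)))
}

#' Cut a mirror-aligned scoring window
#'
#' Rotates the raster by the axis rotation (nearest-neighbour for labels,
#' bilinear for RGB), splits the rows at the mirror row, flips the ventral
#' half vertically, and crops both halves to the lesser half-height and to
#' the window's columns. When the dorsoventral extent is odd the centre row
#' belongs to neither half, so the axis is never double-counted.
#'
#' @param x a [LabelImage-class] or [RGBImage-class].
#' @param axis an [AxisSpec-class].
#' @param window a [WindowSpec-class].
#' @param sampleId,windowId provenance tags.
#' @return a [SymmetryWindow-class].
#' @export
extractWindow <- function(x, axis, window, sampleId = "sample",
                          windowId = "w1") {
  isLabel <- is(x, "LabelImage")
  rot <- rotateRaster(x, axis@rotationDeg)
  d <- if (isLabel) dim(rot@labels) else dim(rot@pixels)[1:2]
  H <- d[1L]; W <- d[2L]

  ## snap the mirror row to the half-integer grid so rows pair exactly
  m <- round(2 * axis@mirrorRow) / 2
  lastAbove <- floor(m - 0.5)
  firstBelow <- ceiling(m + 0.5)
  k <- min(lastAbove, H - firstBelow + 1L)
  if (k < 1L) stop("mirror line leaves no rows to pair", call. = FALSE)
  dorsalRows <- (lastAbove - k + 1L):lastAbove
  ventralRows <- (firstBelow + k - 1L):firstBelow  # flipped about the mirror

  w <- windowWidthPx(window, scaleUmPerPx(x))
  c0 <- round(window@centerCol)
  cols <- (c0 - w %/% 2L):(c0 + w %/% 2L - 1L)
  if (cols[1L] < 1L || cols[length(cols)] > W)
    stop("scoring window falls outside the raster", call. = FALSE)

  take <- function(rows) {
    if (isLabel) rot@labels[rows, cols, drop = FALSE]
    else rot@pixels[rows, cols, , drop = FALSE]
  }
  new("SymmetryWindow", dorsal = take(dorsalRows),
      ventral = take(ventralRows), isLabel = isLabel,
      scaleUmPerPx = scaleUmPerPx(x), sampleId = sampleId,
      windowId = windowId)
}

#' Binary class mask of one window half
#'
#' For a label half, the mask is exact class equality (tolerance ignored).
#' For an RGB half, a pixel matches when every one of its three channels is
#' within `tol` of the target color.
#'
#' @param half a label matrix or H x W x 3 RGB array (one half of a
#'   [SymmetryWindow-class]).
#' @param target a class index (label half) or RGB triple (RGB half).
#' @param tol per-channel tolerance 0..255 (RGB only; default 0).
#' @return logical matrix.
#' @export
classMask <- function(half, target, tol = 0) {
  if (tol < 0 || tol > 255) stop("tol must lie in 0..255", call. = FALSE)
  if (is.matrix(half)) return(half == target)
  stopifnot(length(dim(half)) == 3L, length(target) == 3L)
  out <- abs(half[, , 1L] - target[1L]) <= tol &
    abs(half[, , 2L] - target[2L]) <= tol &
    abs(half[, , 3L] - target[3L]) <= tol
  dim(out) <- dim(half)[1:2]
  out
}

#' Score the mirror symmetry of a window
#'
#' For every class, a mask is computed on each half; `matching` counts the
#' pixels in the mask intersection (the class present at a position and at
#' its mirror partner), `total` the pixels matching the class on either
#' side (mask union; the default), and the per-class score is
#' matching/total — a Jaccard index of the two masks, exactly 1 for a
#' perfect mirror. The combined score pools matching and total counts over
#' all classes. A class absent from both halves has an undefined (NA)
#' score and does not enter the combined pool. With
#' `denominator = "sum"` the total is `|dorsal mask| + |ventral mask|`
#' instead, for sensitivity checks.
#'
#' @param win a [SymmetryWindow-class].
#' @param palette the [ClassPalette-class] defining classes (and colors for
#'   RGB windows).
#' @param tol per-channel color tolerance (RGB windows only).
#' @param denominator `"union"` (default) or `"sum"`.
#' @return a [SymmetryResult-class].
#' @export
scoreWindow <- function(win, palette = defaultPalette(), tol = 0,
                        denominator = c("union", "sum")) {
  stopifnot(is(win, "SymmetryWindow"))
  denominator <- match.arg(denominator)
  if (length(win@dorsal) == 0L) stop("empty window", call. = FALSE)
  cls <- sort(palette@classIndex)
  matching <- total <- numeric(length(cls))
  for (i in seq_along(cls)) {
    if (win@isLabel) {
      md <- classMask(win@dorsal, cls[i])
      mv <- classMask(win@ventral, cls[i])
    } else {
      col <- paletteColor(palette, cls[i])
      md <- classMask(win@dorsal, col, tol)
      mv <- classMask(win@ventral, col, tol)
    }
    matching[i] <- sum(md & mv)
    total[i] <- if (denominator == "union") sum(md | mv)
                else sum(md) + sum(mv)
  }
  score <- ifelse(total > 0, matching / total, NA_real_)
  nm <- paste0("class_", cls)
  names(matching) <- names(total) <- names(score) <- nm
  defined <- total > 0
  new("SymmetryResult", matching = matching, total = total, score = score,
      combined = if (any(defined)) sum(matching[defined]) / sum(total[defined])
                 else NA_real_,
      denominator = denominator, sampleId = win@sampleId,
      windowId = win@windowId)
}

#' Refine the axis rotation against the epidermal contour
#'
#' Formalizes the manual step of tilting the section until the outer
#' contour looks symmetric: searches a grid of rotation offsets in
#' `[-searchDeg, +searchDeg]` and returns the axis whose epidermis-class
#' (class 5) symmetry score inside the window is maximal. Ties go to the
#' smallest absolute offset, negative before positive. With
#' `searchDeg = 0` the input axis is returned unchanged.
#'
#' @param x a [LabelImage-class].
#' @param axis the starting [AxisSpec-class].
#' @param window the [WindowSpec-class] to evaluate in.
#' @param searchDeg half-width of the search range in degrees (>= 0).
#' @param stepDeg grid step in degrees (> 0).
#' @param palette the [ClassPalette-class].
#' @return the refined [AxisSpec-class].
#' @export
refineAngle <- function(x, axis, window, searchDeg = 5, stepDeg = 0.5,
                        palette = defaultPalette()) {
  stopifnot(is(x, "LabelImage"), searchDeg >= 0, stepDeg > 0)
  if (searchDeg == 0) return(axis)
  d <- dim(x@labels)
  epidermisScore <- function(rotation) {
    cand <- axisWithRotation(axis, rotation, d)
    win <- extractWindow(x, cand, window)
    res <- scoreWindow(win, palette)
    unname(res@score["class_5"])
  }
  base <- epidermisScore(axis@rotationDeg)
  if (is.na(base))
    stop("no epidermal contour in window", call. = FALSE)
  offsets <- seq(-searchDeg, searchDeg, by = stepDeg)
  offsets <- offsets[order(abs(offsets), offsets)]  # |angle|, then neg first
  best <- offsets[1L]; bestScore <- -Inf
  for (off in offsets) {
    s <- epidermisScore(axis@rotationDeg + off)
    if (!is.na(s) && s > bestScore) {
      bestScore <- s
      best <- off
    }
  }
  axisWithRotation(axis, axis@rotationDeg + best, d)
}

#' Score several windows of one sample
#'
#' @param x a [LabelImage-class] (or palette-colored [RGBImage-class]).
#' @param axis an [AxisSpec-class].
#' @param windows a list of [WindowSpec-class] objects (>= 1), or a numeric
#'   vector of centre columns (400 um width each).
#' @param tol per-channel color tolerance (RGB only).
#' @param denominator `"union"` or `"sum"`.
#' @param palette the [ClassPalette-class].
#' @param sampleId provenance tag shared by all windows of this sample, so
#'   downstream tables can group scores obtained from the same limb.
#' @return list of [SymmetryResult-class], one per window.
#' @export
scoreSample <- function(x, axis, windows, tol = 0,
                        denominator = c("union", "sum"),
                        palette = defaultPalette(), sampleId = "sample") {
  denominator <- match.arg(denominator)
  if (is.numeric(windows)) windows <- lapply(windows, windowSpec)
  if (length(windows) < 1L)
    stop("at least one window is required", call. = FALSE)
  lapply(seq_along(windows), function(i) {
    win <- extractWindow(x, axis, windows[[i]], sampleId = sampleId,
                         windowId = sprintf("w%02d", i))
    scoreWindow(win, palette, tol, denominator)
  })
}

#' Collect symmetry results into a tidy score table
#'
#' @param results list of [SymmetryResult-class] (possibly from several
#'   samples).
#' @param group group label(s), recycled over results.
#' @return data.frame with columns `group`, `sample`, `window`,
#'   `class_1`..`class_5`, `combined` — the input shape of
#'   [compareToIntact()].
#' @export
scoreTable <- function(results, group = "group") {
  group <- rep_len(group, length(results))
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    row <- data.frame(group = group[i], sample = r@sampleId,
                      window = r@windowId, stringsAsFactors = FALSE)
    for (nm in names(r@score)) row[[nm]] <- unname(r@score[nm])
    row$combined <- r@combined
    row
  }))
}
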