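#' @include AllClasses.R palette.R io.R
NULL

#' Specify a synthetic limb cross-section
#'
#' Defaults describe a 512 x 512 px canvas at 4 um/px (so a 400 um scoring
#' window spans 100 columns) holding a limb-like section: a mirror-symmetric
#' outer contour with an epidermis ring, connective-tissue interior, and a
#' handful of cartilage and muscle elements per half.
#'
#' @param heightPx,widthPx canvas size in pixels.
#' @param scaleUmPerPx micrometres per pixel.
#' @param nCartilage,nMuscle cartilage / muscle elements per half.
#' @param epidermisThicknessPx epidermis ring thickness in pixels.
#' @param asymmetry in [0, 1]: fraction of ventral element placements drawn
#'   independently instead of mirrored from the dorsal half (0 = exact
#'   mirror symmetry of internal tissues, 1 = independent halves).
#' @param seed integer layout seed.
#' @return a [SectionSpec-class].
#' @export
sectionSpec <- function(heightPx = 512L, widthPx = 512L, scaleUmPerPx = 4,
                        nCartilage = 3L, nMuscle = 4L,
                        epidermisThicknessPx = 6L,
                        asymmetry = 0, seed = 1L) {
  new("SectionSpec",
      heightPx = as.integer(heightPx), widthPx = as.integer(widthPx),
      scaleUmPerPx = as.numeric(scaleUmPerPx),
      nCartilage = as.integer(nCartilage), nMuscle = as.integer(nMuscle),
      epidermisThicknessPx = as.integer(epidermisThicknessPx),
      asymmetry = as.numeric(asymmetry), seed = as.integer(seed))
}

#' Specify a trichrome-like stain model
#'
#' @param meanColors 5 x 3 matrix of mean RGB per class (defaults to the
#'   palette display colors).
#' @param multRange (lo, hi) range of the per-sample intensity multiplier,
#'   emulating section-to-section staining intensity variation.
#' @param noiseSd per-pixel, per-channel Gaussian noise sd.
#' @return a [StainModel-class].
#' @export
stainModel <- function(meanColors = defaultPaletteColors(),
                       multRange = c(0.7, 1.3), noiseSd = 4) {
  new("StainModel", meanColors = matrix(as.numeric(meanColors), 5L, 3L),
      multRange = as.numeric(multRange), noiseSd = as.numeric(noiseSd))
}

## radius of the (mirror-symmetric) outer contour at angle theta;
## cos-only harmonics are even in theta, hence symmetric about the mid-row
contourRadius <- function(theta, r0, amps) {
  r <- rep(r0, length(theta))
  for (k in seq_along(amps)) r <- r + r0 * amps[k] * cos(k * theta)
  r
}

ellipseMask <- function(H, W, center, axes, angleRad) {
  rr <- matrix(seq_len(H), H, W) - center[1L]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2L]
  u <- cc * cos(angleRad) + rr * sin(angleRad)
  v <- -cc * sin(angleRad) + rr * cos(angleRad)
  (u / axes[1L])^2 + (v / axes[2L])^2 <= 1
}

## rejection-sample an element center whose bounding circle fits inside the
## interior (contour minus epidermis ring) on the requested side of the
## mirror row; `side` is -1 for dorsal (rows above the mirror), +1 ventral
sampleElementCenter <- function(side, maxAxis, mirrorRow, centerCol,
                                r0, amps, thickness, attempts = 200L) {
  for (i in seq_len(attempts)) {
    dr <- side * runif(1, maxAxis + 1, r0)
    dc <- runif(1, -r0, r0)
    rho <- sqrt(dr^2 + dc^2)
    rEdge <- contourRadius(atan2(dr, dc), r0, amps)
    if (rho + maxAxis + 2 <= rEdge - thickness) {
      return(c(mirrorRow + dr, centerCol + dc))
    }
  }
  stop("cannot fit a tissue element of radius ", round(maxAxis, 1),
       " px inside the section contour", call. = FALSE)
}

#' Generate a ground-truth label section
#'
#' Draws a limb-like transverse section: a smooth, mirror-symmetric outer
#' contour (low-order cosine radial harmonics) bounded by an epidermis ring
#' (class 5) enclosing other connective tissue (class 4) that contains the
#' requested cartilage (class 2) and muscle (class 3) elements, on
#' background (class 1). Internal elements are laid out on the dorsal half
#' and mirrored onto the ventral half; a fraction `asymmetry` of the
#' ventral copies is re-drawn at independent positions and orientations.
#' With `asymmetry = 0` the raster is exactly invariant under reflection
#' about its dorsoventral mid-row. Deterministic given the spec seed.
#'
#' @param spec a [SectionSpec-class].
#' @param palette the [ClassPalette-class] to attach.
#' @return a [LabelImage-class].
#' @export
#' @examples
#' sec <- generateLabelSection(sectionSpec(heightPx = 96, widthPx = 96,
#'                                         nCartilage = 1, nMuscle = 1))
#' table(labels(sec))
generateLabelSection <- function(spec, palette = defaultPalette()) {
  validObject(spec)
  H <- spec@heightPx; W <- spec@widthPx
  mirrorRow <- (H + 1) / 2
  centerCol <- (W + 1) / 2
  thickness <- spec@epidermisThicknessPx

  withr::with_seed(spec@seed, {
    r0 <- 0.40 * min(H, W)
    amps <- runif(3L, -0.06, 0.06)

    dr <- matrix(seq_len(H), H, W) - mirrorRow
    dc <- matrix(seq_len(W), H, W, byrow = TRUE) - centerCol
    rho <- sqrt(dr^2 + dc^2)
    rEdge <- matrix(contourRadius(atan2(dr, dc), r0, amps), H, W)

    lab <- matrix(1L, H, W)
    lab[rho <= rEdge] <- 5L
    lab[rho <= rEdge - thickness] <- 4L

    ## element inventory: size and class first, then dorsal placements
    nEl <- spec@nCartilage + spec@nMuscle
    elClass <- rep(c(2L, 3L), c(spec@nCartilage, spec@nMuscle))
    elements <- vector("list", nEl)
    for (i in seq_len(nEl)) {
      major <- if (elClass[i] == 2L) runif(1, 0.10, 0.16) * r0
               else runif(1, 0.13, 0.20) * r0
      minor <- runif(1, 0.55, 0.95) * major
      ctr <- sampleElementCenter(-1, major, mirrorRow, centerCol,
                                 r0, amps, thickness)
      elements[[i]] <- list(class = elClass[i], axes = c(major, minor),
                            angle = runif(1, 0, pi), center = ctr)
    }

    ## which ventral copies are re-drawn rather than mirrored
    nRedraw <- round(spec@asymmetry * nEl)
    redraw <- if (nRedraw > 0) sample(seq_len(nEl), nRedraw) else integer(0)

    interior <- lab == 4L
    paint <- function(mask, class) {
      sel <- mask & interior
      lab[sel] <<- class
    }
    for (i in seq_len(nEl)) {
      el <- elements[[i]]
      dorsalMask <- ellipseMask(H, W, el$center, el$axes, el$angle)
      paint(dorsalMask, el$class)
      if (i %in% redraw) {
        vCtr <- sampleElementCenter(+1, el$axes[1L], mirrorRow, centerCol,
                                    r0, amps, thickness)
        vAngle <- runif(1, 0, pi)
        paint(ellipseMask(H, W, vCtr, el$axes, vAngle), el$class)
      } else {
        ## mirror the dorsal mask exactly: row i -> 2 * mirrorRow - i
        paint(dorsalMask[H:1, , drop = FALSE], el$class)
      }
    }
    labelImage(lab, palette, spec@scaleUmPerPx)
  })
}

#' Dorsal and ventral end points of a synthetic section
#'
#' The first and last non-background rows along the section's central
#' column — the points a user would click on a real section.
#'
#' @param x a [LabelImage-class].
#' @return list with `dorsal` and `ventral` (row, col) coordinates.
#' @export
sectionEndpoints <- function(x) {
  lab <- x@labels
  ccol <- round((ncol(lab) + 1) / 2)
  fg <- which(lab[, ccol] != x@palette@backgroundIndex)
  if (!length(fg)) stop("no tissue on the central column", call. = FALSE)
  list(dorsal = c(min(fg), ccol), ventral = c(max(fg), ccol))
}

#' Render a label section as a stained RGB image
#'
#' Each pixel's color is the class mean color scaled by a single per-sample
#' intensity multiplier, plus independent Gaussian channel noise, clipped to
#' 0..255. With noise sd 0 and multiplier 1 the render reproduces the class
#' mean colors exactly.
#'
#' @param x a [LabelImage-class].
#' @param stain a [StainModel-class].
#' @param seed integer seed for the multiplier draw and the noise.
#' @param multiplier optional explicit intensity multiplier; if `NULL`, one
#'   is drawn uniformly from the stain model's range.
#' @return an [RGBImage-class].
#' @export
renderStaining <- function(x, stain = stainModel(), seed = 1L,
                           multiplier = NULL) {
  stopifnot(is(x, "LabelImage"), is(stain, "StainModel"))
  validObject(stain)
  idx <- match(x@labels, x@palette@classIndex)
  d <- dim(x@labels)
  withr::with_seed(as.integer(seed), {
    if (is.null(multiplier))
      multiplier <- runif(1, stain@multRange[1L], stain@multRange[2L])
    arr <- array(0, c(d, 3L))
    for (ch in 1:3) {
      base <- stain@meanColors[idx, ch] * multiplier
      if (stain@noiseSd > 0)
        base <- base + rnorm(length(base), sd = stain@noiseSd)
      arr[, , ch] <- pmin(pmax(round(base), 0), 255)
    }
    rgbImage(arr, x@scaleUmPerPx)
  })
}

#' Generate a seeded cohort of synthetic sections
#'
#' One group per asymmetry level, `nPerGroup` samples per group; every
#' sample gets its own layout seed, stain seed and intensity multiplier, all
#' derived reproducibly from the master seed.
#'
#' @param spec a [SectionSpec-class] template (its asymmetry and seed are
#'   overridden per sample).
#' @param groupAsymmetries numeric vector of asymmetry levels, one group
#'   each; names, if present, become group labels.
#' @param nPerGroup samples per group (>= 1).
#' @param seed master seed.
#' @param stain a [StainModel-class].
#' @param palette the shared [ClassPalette-class].
#' @param render if `FALSE`, skip the RGB rendering (ground-truth only).
#' @return list of samples, each a list with `sampleId`, `group`,
#'   `asymmetry`, `labels` ([LabelImage-class]), `rgb` ([RGBImage-class] or
#'   `NULL`), `layoutSeed`, `stainSeed`, `multiplier`.
#' @export
makeCohort <- function(spec, groupAsymmetries, nPerGroup, seed = 1L,
                       stain = stainModel(), palette = defaultPalette(),
                       render = TRUE) {
  stopifnot(nPerGroup >= 1L)
  groups <- if (!is.null(names(groupAsymmetries))) names(groupAsymmetries)
            else sprintf("group%d", seq_along(groupAsymmetries))
  samples <- list()
  withr::with_seed(as.integer(seed), {
    for (g in seq_along(groupAsymmetries)) {
      for (i in seq_len(nPerGroup)) {
        layoutSeed <- sample.int(.Machine$integer.max, 1L)
        stainSeed <- sample.int(.Machine$integer.max, 1L)
        mult <- runif(1, stain@multRange[1L], stain@multRange[2L])
        sspec <- spec
        sspec@asymmetry <- groupAsymmetries[[g]]
        sspec@seed <- layoutSeed
        lab <- generateLabelSection(sspec, palette)
        rgb <- if (render) renderStaining(lab, stain, seed = stainSeed,
                                          multiplier = mult)
               else NULL
        samples[[length(samples) + 1L]] <- list(
          sampleId = sprintf("%s_s%02d", groups[g], i),
          group = groups[g], asymmetry = groupAsymmetries[[g]],
          labels = lab, rgb = rgb,
          layoutSeed = layoutSeed, stainSeed = stainSeed, multiplier = mult)
      }
    }
  })
  samples
}

#' Cohort manifest
#'
#' @param cohort a cohort list from [makeCohort()].
#' @return data.frame with one row per sample (id, group, asymmetry, seeds,
#'   stain multiplier).
#' @export
cohortManifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(sample = s$sampleId, group = s$group,
               asymmetry = s$asymmetry, layout_seed = s$layoutSeed,
               stain_seed = s$stainSeed, multiplier = s$multiplier,
               stringsAsFactors = FALSE)
  }))
}
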