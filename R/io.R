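#' @include AllClasses.R palette.R
NULL

#' Construct an RGB section image
#'
#' @param pixels H x W x 3 numeric array, values 0..255.
#' @param scaleUmPerPx micrometres per pixel.
#' @return an [RGBImage-class].
#' @export
rgbImage <- function(pixels, scaleUmPerPx) {
  storage.mode(pixels) <- "integer"
  new("RGBImage", pixels = pixels, scaleUmPerPx = as.numeric(scaleUmPerPx))
}

#' Construct a label image
#'
#' @param labels H x W matrix of class indices.
#' @param palette a [ClassPalette-class] (default [defaultPalette()]).
#' @param scaleUmPerPx micrometres per pixel.
#' @return a [LabelImage-class].
#' @export
labelImage <- function(labels, palette = defaultPalette(), scaleUmPerPx) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  new("LabelImage", labels = labels, palette = palette,
      scaleUmPerPx = as.numeric(scaleUmPerPx))
}

imageFormatFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) "png"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else stop("unsupported image format: ", ext,
            " (expected PNG or TIFF)", call. = FALSE)
}

readRaster255 <- function(path) {
  arr <- switch(imageFormatFromPath(path),
                png = png::readPNG(path),
                tiff = tiff::readTIFF(path))
  if (is.matrix(arr)) dim(arr) <- c(dim(arr), 1L)
  round(arr * 255)
}

#' Read an RGB section image from PNG or TIFF
#'
#' A fourth (alpha) channel, if present, is discarded. Images with fewer
#' than three channels are rejected: the pipeline operates on color
#' sections. The physical scale is not stored in the raster and must be
#' supplied, either directly or via a JSON sidecar (see
#' [readSectionConfig()]).
#'
#' @param path PNG or TIFF file.
#' @param scaleUmPerPx micrometres per pixel; if `NULL`, read from the
#'   sidecar `<path>.json`.
#' @return an [RGBImage-class].
#' @export
readRGBSection <- function(path, scaleUmPerPx = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  arr <- readRaster255(path)
  nc <- dim(arr)[3L]
  if (nc == 4L) arr <- arr[, , 1:3, drop = FALSE]
  else if (nc != 3L)
    stop("unsupported channel count (", nc, "): need a 3-channel image",
         call. = FALSE)
  if (is.null(scaleUmPerPx)) {
    cfg <- readSectionConfig(paste0(path, ".json"))
    scaleUmPerPx <- cfg$scale_um_per_px
  }
  rgbImage(arr, scaleUmPerPx)
}

#' Write an RGB section image
#'
#' Lossless 8-bit output: `readRGBSection(writeRGBSection(x, p))` returns
#' the identical pixel array.
#'
#' @param x an [RGBImage-class].
#' @param path output PNG or TIFF path (format chosen by extension).
#' @return `path`, invisibly.
#' @export
writeRGBSection <- function(x, path) {
  stopifnot(is(x, "RGBImage"))
  arr <- x@pixels / 255
  switch(imageFormatFromPath(path),
         png = png::writePNG(arr, path),
         tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L))
  invisible(path)
}

#' Read a class-label image
#'
#' The file must be an RGB (or RGBA) raster whose colors all match palette
#' colors exactly; each color decodes to its class index. A color absent
#' from the palette is an error naming the color and the first pixel
#' coordinate at which it occurs.
#'
#' @param path PNG or TIFF file of palette-colored class labels.
#' @param palette the [ClassPalette-class] to decode against.
#' @param scaleUmPerPx micrometres per pixel; if `NULL`, read from the
#'   sidecar `<path>.json`.
#' @return a [LabelImage-class].
#' @export
readLabelImage <- function(path, palette = defaultPalette(),
                           scaleUmPerPx = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  arr <- readRaster255(path)
  nc <- dim(arr)[3L]
  if (nc == 4L) arr <- arr[, , 1:3, drop = FALSE]
  else if (nc != 3L)
    stop("unsupported channel count (", nc, ") in label image", call. = FALSE)
  keys <- paletteColorKeys(palette)
  px <- paste(arr[, , 1L], arr[, , 2L], arr[, , 3L], sep = ",")
  cls <- keys[px]
  if (anyNA(cls)) {
    bad <- which(is.na(cls))[1L]
    h <- dim(arr)[1L]
    r <- (bad - 1L) %% h + 1L
    c <- (bad - 1L) %/% h + 1L
    stop(sprintf(
      "color rgb(%s) at pixel (%d, %d) is not in the class palette",
      px[bad], r, c), call. = FALSE)
  }
  lab <- matrix(unname(cls), nrow = dim(arr)[1L], ncol = dim(arr)[2L])
  if (is.null(scaleUmPerPx)) {
    cfg <- readSectionConfig(paste0(path, ".json"))
    scaleUmPerPx <- cfg$scale_um_per_px
  }
  labelImage(lab, palette, scaleUmPerPx)
}

#' Write a class-label image
#'
#' Each class is rendered as its exact palette color, so the file
#' round-trips bit-exactly through [readLabelImage()].
#'
#' @param x a [LabelImage-class].
#' @param path output PNG or TIFF path.
#' @return `path`, invisibly.
#' @export
writeLabelImage <- function(x, path) {
  stopifnot(is(x, "LabelImage"))
  labelImageToRGB(x) |> writeRGBSection(path)
  invisible(path)
}

#' Render a label image as palette colors
#'
#' @param x a [LabelImage-class].
#' @return an [RGBImage-class] in which every pixel carries its class's
#'   exact palette color.
#' @export
labelImageToRGB <- function(x) {
  idx <- match(x@labels, x@palette@classIndex)
  d <- dim(x@labels)
  arr <- array(0L, c(d, 3L))
  for (ch in 1:3) arr[, , ch] <- x@palette@colors[idx, ch]
  rgbImage(arr, x@scaleUmPerPx)
}

#' Read / write a JSON section sidecar
#'
#' The sidecar carries what the raster cannot: the physical scale and the
#' user-placed dorsal and ventral end points, as
#' `{"scale_um_per_px": ..., "dorsal_point": [row, col],
#' "ventral_point": [row, col]}` (1-based pixel coordinates).
#'
#' @param path JSON file path.
#' @return `readSectionConfig` returns the parsed list;
#'   `writeSectionConfig` returns `path` invisibly.
#' @export
readSectionConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read sidecar config: ", path,
                               call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$scale_um_per_px) || cfg$scale_um_per_px <= 0)
    stop("sidecar must declare a positive scale_um_per_px", call. = FALSE)
  cfg
}

#' @rdname readSectionConfig
#' @param config a list with at least `scale_um_per_px`, plus optional
#'   `dorsal_point` and `ventral_point`.
#' @export
writeSectionConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
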