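#' @include AllClasses.R
NULL

#' Construct a tissue class palette
#'
#' @param classIndex integer class indices (must be 1..5, no repeats).
#' @param className class names, one per index.
#' @param colors 5 x 3 numeric matrix of RGB display colors (0..255),
#'   pairwise distinct.
#' @param backgroundIndex which class is background (default 1).
#' @return a validated [ClassPalette-class].
#' @export
#' @examples
#' classPaletteSpec()
classPaletteSpec <- function(classIndex = 1:5,
                             className = c("background", "cartilage",
                                           "muscle",
                                           "other connective tissue",
                                           "epidermis"),
                             colors = defaultPaletteColors(),
                             backgroundIndex = 1L) {
  new("ClassPalette",
      classIndex = as.integer(classIndex),
      className = as.character(className),
      colors = matrix(as.numeric(colors), nrow = length(classIndex), ncol = 3L,
                      dimnames = list(className, c("r", "g", "b"))),
      backgroundIndex = as.integer(backgroundIndex))
}

#' Default display colors for the five tissue classes
#'
#' Trichrome-inspired display colors: white background, blue cartilage, red
#' muscle, pink connective tissue, dark purple epidermis. They are display
#' and rendering colors, not a model of real Masson staining.
#'
#' @return 5 x 3 numeric matrix of RGB values.
#' @export
defaultPaletteColors <- function() {
  rbind(
    background = c(255, 255, 255),
    cartilage = c(70, 130, 180),
    muscle = c(178, 34, 34),
    `other connective tissue` = c(235, 150, 170),
    epidermis = c(110, 30, 90)
  )
}

#' The package-wide default five-class palette
#'
#' @return the default [ClassPalette-class] (background, cartilage, muscle,
#'   other connective tissue, epidermis).
#' @export
defaultPalette <- function() classPaletteSpec()

#' Look up the palette color of a class
#'
#' @param palette a [ClassPalette-class].
#' @param classIndex a single class index.
#' @return length-3 numeric RGB vector.
#' @export
paletteColor <- function(palette, classIndex) {
  i <- match(classIndex, palette@classIndex)
  if (is.na(i)) stop("class index ", classIndex, " not in palette")
  palette@colors[i, ]
}

## key "r,g,b" -> class index; used for exact color -> class decoding
paletteColorKeys <- function(palette) {
  structure(palette@classIndex,
            names = apply(palette@colors, 1L, paste, collapse = ","))
}
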