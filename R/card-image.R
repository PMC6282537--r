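#' Create and interrogate WSP card images
#'
#' @description
#' `wspCard()` wraps a grayscale intensity matrix (0-255) and the scan
#' resolution into a [WSPCard-class] object. `pixelPitch()` returns the
#' physical pixel size in micrometres (25400/dpi; 600 dpi scans have a
#' 42.33 um pitch) and `cardArea()` the physical card area in cm2.
#'
#' `blankCard()` builds an all-background card of the given pixel
#' dimensions, the canvas used by the synthetic stain generators.
#'
#' @param pixels numeric matrix of intensities in [0, 255] (rows = y,
#'   columns = x).
#' @param dpi scan resolution in dots per inch.
#' @param widthPx,heightPx canvas size in pixels.
#' @param background background intensity (default 255, unstained WSP
#'   scans are light).
#' @param object a [WSPCard-class] object.
#' @return `wspCard()`/`blankCard()` a [WSPCard-class]; `pixelPitch()`
#'   micrometres per pixel; `cardArea()` cm2.
#' @examples
#' card <- blankCard(200, 100, dpi = 600)
#' pixelPitch(card)   # 42.33 um
#' cardArea(card)     # 0.358 cm2
#' @name wspCard
#' @export
wspCard <- function(pixels, dpi = 600) {
  storage.mode(pixels) <- "double"
  new("WSPCard", pixels = pixels, dpi = dpi)
}

#' @rdname wspCard
#' @export
blankCard <- function(widthPx, heightPx, dpi = 600, background = 255) {
  wspCard(matrix(background, nrow = heightPx, ncol = widthPx), dpi = dpi)
}

#' @rdname wspCard
setMethod("pixelPitch", "WSPCard", function(object) 25400 / object@dpi)

#' @rdname wspCard
setMethod("cardArea", "WSPCard", function(object) {
  # um^2 per pixel * n pixels -> cm^2 (1 cm^2 = 1e8 um^2)
  length(object@pixels) * (25400 / object@dpi)^2 * 1e-8
})

#' @rdname wspCard
#' @export
cardPixels <- function(object) object@pixels

setMethod("show", "WSPCard", function(object) {
  cat(sprintf("WSPCard: %d x %d px at %g dpi (pitch %.2f um, %.3f cm2)\n",
              ncol(object@pixels), nrow(object@pixels), object@dpi,
              pixelPitch(object), cardArea(object)))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@pixels), max(object@pixels)))
})

#' Read and write card scans
#'
#' @description
#' `readCardImage()` loads a grayscale scan (PNG, TIFF or JPEG) as a
#' [WSPCard-class]. Colour images are converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B). The scan resolution is not inferred
#' from file metadata and must be supplied. `writeCardImage()` writes a
#' card as PNG (the fixture format used by the experiment drivers).
#'
#' @param path file path.
#' @param dpi scan resolution in dots per inch.
#' @param card a [WSPCard-class] object.
#' @return `readCardImage()` a [WSPCard-class]; `writeCardImage()` the
#'   path, invisibly.
#' @export
readCardImage <- function(path, dpi) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff", "jpg", "jpeg"))
    stop("unsupported image format '", ext,
         "': supported formats are PNG, TIFF and JPEG")
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    nch <- dim(dat)[3]
    w <- if (nch >= 3) c(0.2126, 0.7152, 0.0722) else rep(1 / nch, nch)
    lum <- dat[, , 1] * w[1]
    for (k in seq_len(min(nch, 3))[-1]) lum <- lum + dat[, , k] * w[k]
    dat <- lum
  }
  # EBImage stores images x-by-y in [0,1]; transpose to rows = y
  wspCard(t(dat) * 255, dpi = dpi)
}

#' @rdname readCardImage
#' @export
writeCardImage <- function(card, path) {
  stopifnot(is(card, "WSPCard"))
  EBImage::writeImage(EBImage::Image(t(card@pixels) / 255), path)
  invisible(path)
}
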