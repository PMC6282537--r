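# Pixel (x, y) is centred at coordinate (x, y) in 0-based pixel units;
# a pixel belongs to a circle when its centre lies within the boundary
# (inclusive, with a 1e-12 relative tolerance so exact tangencies
# rasterize symmetrically despite floating-point rounding).
# Deterministic and directly checkable by brute force.
circlePixelIndices <- function(cx, cy, radiusPx, widthPx, heightPx) {
  x0 <- max(0L, floor(cx - radiusPx))
  x1 <- min(widthPx - 1L, ceiling(cx + radiusPx))
  y0 <- max(0L, floor(cy - radiusPx))
  y1 <- min(heightPx - 1L, ceiling(cy + radiusPx))
  if (x1 < x0 || y1 < y0) return(integer(0))
  xs <- x0:x1
  ys <- y0:y1
  inside <- outer((ys - cy)^2, (xs - cx)^2, "+") <=
    radiusPx^2 * (1 + 1e-12)
  # linear indices into the heightPx x widthPx pixel matrix
  idx <- which(inside)
  if (length(idx) == 0L) return(integer(0))
  row <- ((idx - 1L) %% length(ys)) + y0 + 1L
  col <- ((idx - 1L) %/% length(ys)) + x0 + 1L
  (col - 1L) * heightPx + row
}

#' Rasterize a circular stain onto a card
#'
#' Draws a filled circle of the given physical diameter: every pixel
#' whose centre lies within the circle (boundary inclusive) is set to
#' \code{intensity}. Pixel centres sit at integer 0-based coordinates, so
#' a circle of diameter one pixel pitch centred on a pixel centre marks
#' exactly that pixel.
#'
#' @param card a [WSPCard-class] object.
#' @param centerX,centerY circle centre in 0-based pixel coordinates
#'   (may be fractional).
#' @param diameter stain diameter in micrometres; > 0.
#' @param intensity intensity to write (default 0, a saturated stain).
#' @return the modified [WSPCard-class].
#' @examples
#' card <- blankCard(40, 40, dpi = 600)
#' card <- rasterizeCircle(card, 20, 20, diameter = 500)
#' sum(cardPixels(card) == 0)  # pixel count of the stain
#' @export
rasterizeCircle <- function(card, centerX, centerY, diameter,
                            intensity = 0) {
  stopifnot(is(card, "WSPCard"), length(diameter) == 1L, diameter > 0)
  pitch <- pixelPitch(card)
  r <- diameter / (2 * pitch)
  h <- nrow(card@pixels); w <- ncol(card@pixels)
  if (centerX - r < -0.5 || centerX + r > w - 0.5 ||
      centerY - r < -0.5 || centerY + r > h - 0.5)
    stop("circle of diameter ", diameter, " um does not fit at (",
         centerX, ", ", centerY, ") on a ", w, " x ", h, " px card")
  idx <- circlePixelIndices(centerX, centerY, r, w, h)
  card@pixels[idx] <- intensity
  card
}

#' Generate a pair of equal stains, tangent or separated
#'
#' Reproduces the touching-droplet validation fixture: two circular
#' stains of equal diameter placed either tangent (touching at one point
#' but not overlapping, so their combined extent is 2d wide and d tall)
#' or separated by at least two pixel pitches of background. For the
#' tangent pair the point of tangency is snapped to a pixel centre, so
#' the shared boundary pixel belongs to both circles and connected-
#' component labelling sees a single merged stain, mirroring
#' deposit-scanning software's assumption that touching stains are one
#' deposit.
#'
#' @param diameter stain diameter in micrometres.
#' @param widthPx,heightPx canvas size in pixels.
#' @param dpi scan resolution.
#' @param touching logical: tangent pair (TRUE) or separated pair.
#' @param intensity stain intensity (default 0).
#' @return list with elements \code{card} (a [WSPCard-class]) and
#'   \code{centers} (2 x 2 matrix of circle centres, pixel coordinates).
#' @export
generateTouchingPair <- function(diameter, widthPx, heightPx, dpi = 600,
                                 touching = TRUE, intensity = 0) {
  card <- blankCard(widthPx, heightPx, dpi = dpi)
  pitch <- pixelPitch(card)
  rPx <- diameter / (2 * pitch)
  cy <- round((heightPx - 1) / 2)
  if (touching) {
    # tangent point at a pixel centre; centres one diameter apart
    tx <- round((widthPx - 1) / 2)
    centers <- rbind(c(tx - rPx, cy), c(tx + rPx, cy))
  } else {
    gap <- 2 * rPx + 3  # >= 2 pixel pitches of clear background
    mid <- (widthPx - 1) / 2
    centers <- rbind(c(mid - gap / 2, cy), c(mid + gap / 2, cy))
  }
  for (i in 1:2)
    card <- rasterizeCircle(card, centers[i, 1], centers[i, 2], diameter,
                            intensity = intensity)
  list(card = card, centers = centers)
}

#' Generate a synthetic card of non-overlapping circular stains
#'
#' Places circular stains of the requested physical diameters at random
#' non-overlapping positions (with at least two pixel pitches of
#' background between stain boundaries so segmentation recovers each
#' stain as its own component). Placement is reproducible from the seed.
#'
#' @param stainDiameters numeric vector of stain diameters in
#'   micrometres; may be empty (blank card).
#' @param widthPx,heightPx canvas size in pixels.
#' @param dpi scan resolution.
#' @param seed integer seed for placement.
#' @param intensity stain intensity (default 0).
#' @param maxTries placement attempts per stain before giving up.
#' @return list with \code{card} (a [WSPCard-class]) and \code{truth}, a
#'   ground-truth data.frame (\code{stain_id}, \code{diameter_um},
#'   \code{center_x}, \code{center_y}, \code{pixel_count}); pixel counts
#'   come from the same centre-inclusion rule as the rasterizer.
#' @export
generateCard <- function(stainDiameters, widthPx, heightPx, dpi = 600,
                         seed = 1L, intensity = 0, maxTries = 200L) {
  card <- blankCard(widthPx, heightPx, dpi = dpi)
  pitch <- pixelPitch(card)
  n <- length(stainDiameters)
  truth <- data.frame(stain_id = integer(0), diameter_um = numeric(0),
                      center_x = numeric(0), center_y = numeric(0),
                      pixel_count = integer(0))
  if (n == 0L) return(list(card = card, truth = truth))
  rPx <- stainDiameters / (2 * pitch)
  ord <- order(rPx, decreasing = TRUE)  # place large stains first
  centers <- matrix(NA_real_, n, 2)
  set.seed(seed)
  for (i in ord) {
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      cx <- runif(1, rPx[i], widthPx - 1 - rPx[i])
      cy <- runif(1, rPx[i], heightPx - 1 - rPx[i])
      done <- which(!is.na(centers[, 1]))
      if (length(done) == 0L ||
          all(sqrt((centers[done, 1] - cx)^2 + (centers[done, 2] - cy)^2) >
              rPx[done] + rPx[i] + 3)) {
        centers[i, ] <- c(cx, cy)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place a stain of ", stainDiameters[i],
           " um after ", maxTries, " tries; use a larger card or fewer stains")
  }
  counts <- integer(n)
  for (i in seq_len(n)) {
    idx <- circlePixelIndices(centers[i, 1], centers[i, 2], rPx[i],
                              widthPx, heightPx)
    counts[i] <- length(idx)
    card@pixels[idx] <- intensity
  }
  truth <- data.frame(stain_id = seq_len(n),
                      diameter_um = stainDiameters,
                      center_x = centers[, 1], center_y = centers[, 2],
                      pixel_count = counts)
  list(card = card, truth = truth)
}
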