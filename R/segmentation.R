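#' Segmentation configuration constructor
#'
#' @param thresholdMode "automatic" (between-class-variance maximisation,
#'   i.e. Otsu's method on the 256-level histogram) or "fixed".
#' @param fixedThreshold intensity in [0, 255]; the fixed threshold, also
#'   the fallback when automatic thresholding is impossible.
#' @param connectivity 4 or 8 (default 8).
#' @param minPixels minimum component size in pixels (default 1; at
#'   600 dpi one pixel is 42.33 um, already above typical minimum
#'   detectable droplet claims, so 1 is the honest floor).
#' @param stainsDarker logical; stains are the darker class (TRUE for
#'   scanned WSP).
#' @return a [SegmentationConfig-class] object.
#' @export
segmentationConfig <- function(thresholdMode = c("automatic", "fixed"),
                               fixedThreshold = 128,
                               connectivity = 8,
                               minPixels = 1,
                               stainsDarker = TRUE) {
  new("SegmentationConfig",
      thresholdMode = match.arg(thresholdMode),
      fixedThreshold = fixedThreshold,
      connectivity = as.integer(connectivity),
      minPixels = as.integer(minPixels),
      stainsDarker = stainsDarker)
}

#' Binarize a card scan into a stain mask
#'
#' Separates stain from background. In automatic mode the global
#' threshold maximises the between-class variance of the intensity
#' histogram (Otsu's method, via \code{EBImage::otsu}), which is
#' parameter-free for the bimodal histograms of WSP scans. Pixels on the
#' darker side of the threshold are stains when \code{stainsDarker}. A
#' uniform image cannot be thresholded automatically; it falls back to
#' the fixed threshold with a warning.
#'
#' @param card a [WSPCard-class] object.
#' @param config a [SegmentationConfig-class] object.
#' @return logical matrix, TRUE at stain pixels.
#' @export
binarize <- function(card, config = segmentationConfig()) {
  stopifnot(is(card, "WSPCard"), is(config, "SegmentationConfig"))
  px <- card@pixels
  thr <- config@fixedThreshold
  if (config@thresholdMode == "automatic") {
    if (diff(range(px)) == 0) {
      warning("uniform image: automatic threshold undefined, ",
              "falling back to fixed threshold ", config@fixedThreshold)
    } else {
      thr <- EBImage::otsu(EBImage::Image(t(px) / 255), range = c(0, 1),
                           levels = 256) * 255
    }
  }
  if (config@stainsDarker) px <= thr else px >= thr
}

# Connected components of a logical mask under 4- or 8-connectivity.
# Adjacent stained pixels are joined by edges and components are read off
# the pixel-adjacency graph. Returns an integer matrix of labels
# (0 = background), labelled in first-pixel order.
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  h <- nrow(mask); w <- ncol(mask)
  on <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(on) == 0L) return(lab)
  id <- match(seq_len(h * w), on)  # linear index -> vertex id
  edgePairs <- function(dr, dc) {
    rows <- ((on - 1L) %% h) + 1L
    cols <- ((on - 1L) %/% h) + 1L
    r2 <- rows + dr; c2 <- cols + dc
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    keep <- mask[nb]
    cbind(id[on[ok][keep]], id[nb[keep]])
  }
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L)
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(offsets, function(o) edgePairs(o[1], o[2])))
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel in order of first appearance (column-major scan order)
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  lab[on] <- relab[memb]
  lab
}

#' Extract stain records from a binary mask
#'
#' Labels connected components of the stain mask (4- or 8-connectivity
#' per the configuration), discards components below \code{minPixels},
#' and converts pixel counts to physical areas through the pixel pitch
#' (25400/dpi um). Stain diameters are equivalent-circle diameters.
#'
#' @param mask logical stain mask from [binarize()].
#' @param dpi scan resolution used for the mask's card.
#' @param config a [SegmentationConfig-class] object.
#' @return data.frame with one row per stain: \code{stain_id},
#'   \code{pixel_count}, \code{area_um2}, \code{stain_diameter_um},
#'   \code{centroid_x}, \code{centroid_y} (0-based pixel coordinates).
#' @examples
#' card <- rasterizeCircle(blankCard(40, 40, dpi = 600), 20, 20, 500)
#' mask <- binarize(card)
#' extractStains(mask, dpi = 600)
#' @export
extractStains <- function(mask, dpi, config = segmentationConfig()) {
  stopifnot(is.logical(mask), is.matrix(mask), dpi > 0)
  pitch <- 25400 / dpi
  lab <- labelComponents(mask, config@connectivity)
  on <- which(lab > 0L)
  if (length(on) == 0L)
    return(data.frame(stain_id = integer(0), pixel_count = integer(0),
                      area_um2 = numeric(0), stain_diameter_um = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0)))
  h <- nrow(mask)
  lv <- lab[on]
  rows <- ((on - 1L) %% h)        # 0-based y
  cols <- ((on - 1L) %/% h)       # 0-based x
  counts <- tabulate(lv)
  cx <- tapply(cols, lv, mean)
  cy <- tapply(rows, lv, mean)
  keep <- which(counts >= config@minPixels)
  out <- data.frame(stain_id = seq_along(keep),
                    pixel_count = counts[keep],
                    area_um2 = counts[keep] * pitch^2,
                    stain_diameter_um =
                      stainDiameterFromArea(counts[keep] * pitch^2),
                    centroid_x = as.numeric(cx[as.character(keep)]),
                    centroid_y = as.numeric(cy[as.character(keep)]))
  rownames(out) <- NULL
  out
}
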