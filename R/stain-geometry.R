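#' Equivalent-circle stain diameter from stain area
#'
#' A stain of area \eqn{A} (um^2) is assigned the diameter of the circle
#' with the same area, \eqn{d_s = 2\sqrt{A/\pi}} um.
#'
#' @param area numeric, stain area(s) in um^2; >= 0.
#' @return numeric, stain diameter(s) in um; an area of 0 maps to 0.
#' @examples
#' stainDiameterFromArea(pi * 50^2)  # 100
#' @export
stainDiameterFromArea <- function(area) {
  if (any(!is.finite(area)) || any(area < 0))
    stop("stain areas must be non-negative and finite")
  2 * sqrt(area / pi)
}

#' Spherical droplet volume from droplet diameter
#'
#' Assumes spherical droplets: \eqn{V = (\pi/6) d^3} with \eqn{d} in um,
#' converted to microlitres (1 uL = 1e9 um^3).
#'
#' @param diameter numeric, droplet diameter(s) in um; >= 0.
#' @return numeric, volume(s) in uL.
#' @examples
#' dropletVolume(100)   # 5.236e-4 uL
#' dropletVolume(1000)  # 0.5236 uL
#' @export
dropletVolume <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter < 0))
    stop("droplet diameters must be non-negative and finite")
  (pi / 6) * diameter^3 * 1e-9
}

#' Add droplet diameter and volume columns to a stain table
#'
#' Takes a stain table (as produced by [extractStains()], with columns
#' \code{area_um2} and \code{stain_diameter_um}) and appends
#' \code{droplet_diameter_um} and \code{volume_uL} under the given
#' spread-factor model.
#'
#' @param stains data.frame with columns \code{area_um2},
#'   \code{stain_diameter_um}.
#' @param model a [SpreadFactorModel-class] object.
#' @return the stain table with droplet estimate columns appended.
#' @export
addDropletEstimates <- function(stains, model) {
  stopifnot(is.data.frame(stains),
            all(c("area_um2", "stain_diameter_um") %in% names(stains)))
  if (nrow(stains) == 0L) {
    stains$droplet_diameter_um <- numeric(0)
    stains$volume_uL <- numeric(0)
    return(stains)
  }
  d <- dropletDiameter(model, area = stains$area_um2,
                       stainDiameter = stains$stain_diameter_um)
  stains$droplet_diameter_um <- d
  stains$volume_uL <- dropletVolume(d)
  stains
}

#' Per-card spray metrics from a stain table
#'
#' Computes the card-level summary: coverage (100 * stained pixels /
#' total pixels), droplet density (number of stains per cm2 of card) and
#' liquid deposition (sum of per-droplet spherical volumes per cm2,
#' uL cm-2). Cards with coverage above \code{coverageThreshold} are
#' flagged: at high coverage stains merge and volume estimates become
#' unreliable, so flagged cards are conventionally excluded from residue
#' calibration.
#'
#' @param stains stain table (see [extractStains()]); droplet estimates
#'   are computed with \code{model} if not already present.
#' @param cardAreaCm2 physical card area in cm2; > 0.
#' @param stainedPixels number of stained pixels on the card.
#' @param totalPixels total number of card pixels; > 0.
#' @param model a [SpreadFactorModel-class] object.
#' @param coverageThreshold coverage percentage above which the card is
#'   flagged (default 30).
#' @return a [CardMetrics-class] object. An empty stain table yields zero
#'   metrics (not an error).
#' @examples
#' st <- data.frame(area_um2 = pi * 50^2, stain_diameter_um = 100)
#' cardMetrics(st, cardAreaCm2 = 1, stainedPixels = 5, totalPixels = 1e4,
#'             model = constantSpreadFactor())
#' @export
cardMetrics <- function(stains, cardAreaCm2, stainedPixels, totalPixels,
                        model = constantSpreadFactor(),
                        coverageThreshold = 30) {
  stopifnot(length(cardAreaCm2) == 1L, cardAreaCm2 > 0,
            length(totalPixels) == 1L, totalPixels > 0,
            stainedPixels >= 0, stainedPixels <= totalPixels)
  if (!"volume_uL" %in% names(stains))
    stains <- addDropletEstimates(stains, model)
  cov <- 100 * stainedPixels / totalPixels
  new("CardMetrics",
      coveragePct = cov,
      densityPerCm2 = nrow(stains) / cardAreaCm2,
      depositionUlPerCm2 = sum(stains$volume_uL) / cardAreaCm2,
      nStains = nrow(stains),
      cardAreaCm2 = cardAreaCm2,
      highCoverageFlag = cov > coverageThreshold)
}

#' Accessors for fitted objects
#'
#' @param object a [CardMetrics-class] or [CorrectionModel-class] object.
#' @return the corresponding scalar summary.
#' @name accessors
#' @aliases coverage dropletDensity deposition nStains highCoverage
#'   correctionFactor
NULL

#' @rdname accessors
setMethod("coverage", "CardMetrics", function(object) object@coveragePct)

#' @rdname accessors
setMethod("dropletDensity", "CardMetrics",
  function(object) object@densityPerCm2)

#' @rdname accessors
setMethod("deposition", "CardMetrics",
  function(object) object@depositionUlPerCm2)

#' @rdname accessors
setMethod("nStains", "CardMetrics", function(object) object@nStains)

#' @rdname accessors
setMethod("highCoverage", "CardMetrics",
  function(object) object@highCoverageFlag)

setMethod("show", "CardMetrics", function(object) {
  cat("CardMetrics (", format(object@cardAreaCm2, digits = 4),
      " cm2 card)\n", sep = "")
  cat(sprintf("  coverage:   %.2f %%%s\n", object@coveragePct,
              if (object@highCoverageFlag) "  [high-coverage flag]" else ""))
  cat(sprintf("  density:    %.2f stains cm-2  (n = %d)\n",
              object@densityPerCm2, object@nStains))
  cat(sprintf("  deposition: %.4g uL cm-2\n", object@depositionUlPerCm2))
  if (!is.na(object@residueUgPerCm2))
    cat(sprintf("  residue:    %.4g ug cm-2\n", object@residueUgPerCm2))
})

#' @describeIn cardMetrics flatten one or more CardMetrics into the card
#'   summary table (columns \code{card_id}, \code{coverage_pct},
#'   \code{density_per_cm2}, \code{deposition_uL_per_cm2}, \code{n_stains},
#'   \code{high_coverage_flag}).
#' @param metrics a CardMetrics object or list of them.
#' @param cardIds optional character vector of card identifiers.
#' @export
cardSummaryTable <- function(metrics, cardIds = NULL) {
  if (is(metrics, "CardMetrics")) metrics <- list(metrics)
  if (is.null(cardIds)) cardIds <- sprintf("card%03d", seq_along(metrics))
  out <- data.frame(
    card_id = cardIds,
    coverage_pct = vapply(metrics, coverage, 0),
    density_per_cm2 = vapply(metrics, dropletDensity, 0),
    deposition_uL_per_cm2 = vapply(metrics, deposition, 0),
    n_stains = vapply(metrics, nStains, 0L),
    high_coverage_flag = vapply(metrics, highCoverage, TRUE),
    stringsAsFactors = FALSE)
  res <- vapply(metrics, function(m) m@residueUgPerCm2, 0)
  if (any(!is.na(res))) out$residue_ug_per_cm2 <- res
  out
}
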