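#' Spread-factor models
#'
#' A spread factor relates the size of the stain a droplet leaves on
#' water-sensitive paper to the diameter of the original airborne droplet.
#' Two model families are supported:
#' \describe{
#'   \item{\code{ConstantSpreadFactor}}{a single power law applied to the
#'     stain area: droplet diameter \eqn{d = SF \cdot A^{b}} with stain
#'     area \eqn{A} in \eqn{\mu m^2}, factor \eqn{SF} (default 1.06) and
#'     exponent \eqn{b} (default 0.455).}
#'   \item{\code{BinnedSpreadFactor}}{a lookup table of spread factors by
#'     stain-diameter bin: droplet diameter \eqn{d = d_s / SF(d_s)} where
#'     \eqn{d_s} is the equivalent-circle stain diameter in \eqn{\mu m}.}
#' }
#'
#' @slot sf numeric(1), multiplicative factor of the power law; > 0.
#' @slot exponent numeric(1), power-law exponent in (0, 1).
#' @slot upper numeric, strictly increasing upper stain-diameter bin
#'   bounds in \eqn{\mu m}; bins are half-open \code{(lower, upper]}.
#' @slot factors numeric, spread factor per bin; all >= 1.
#'
#' @seealso [constantSpreadFactor()], [binnedSpreadFactor()],
#'   [dropletDiameter()]
#' @name SpreadFactorModel-class
#' @aliases ConstantSpreadFactor-class BinnedSpreadFactor-class
#' @exportClass SpreadFactorModel ConstantSpreadFactor BinnedSpreadFactor
setClass("SpreadFactorModel", representation("VIRTUAL"))

setClass("ConstantSpreadFactor",
  contains = "SpreadFactorModel",
  representation(sf = "numeric", exponent = "numeric"),
  prototype(sf = 1.06, exponent = 0.455))

setValidity("ConstantSpreadFactor", function(object) {
  msg <- character()
  if (length(object@sf) != 1L || !is.finite(object@sf) || object@sf <= 0)
    msg <- c(msg, "'sf' must be a single positive number")
  if (length(object@exponent) != 1L || !is.finite(object@exponent) ||
      object@exponent <= 0 || object@exponent >= 1)
    msg <- c(msg, "'exponent' must be a single number in (0, 1)")
  if (length(msg)) msg else TRUE
})

setClass("BinnedSpreadFactor",
  contains = "SpreadFactorModel",
  representation(upper = "numeric", factors = "numeric"))

setValidity("BinnedSpreadFactor", function(object) {
  msg <- character()
  if (length(object@upper) == 0L)
    msg <- c(msg, "at least one bin is required")
  if (length(object@upper) != length(object@factors))
    msg <- c(msg, "'upper' and 'factors' must have equal length")
  if (any(!is.finite(object@upper)) || any(diff(object@upper) <= 0) ||
      any(object@upper <= 0))
    msg <- c(msg, "'upper' bounds must be positive and strictly increasing")
  if (any(!is.finite(object@factors)) || any(object@factors < 1))
    msg <- c(msg, "'factors' must all be >= 1")
  if (length(msg)) msg else TRUE
})

#' Water-sensitive paper card image
#'
#' A grayscale raster scan of a WSP card together with the scan
#' resolution. Pixel values are intensities in [0, 255] (stains are dark
#' on a light background for scanned WSP). The physical pixel pitch is
#' \code{25400/dpi} micrometres; pixel indices are 0-based with pixel
#' \code{(x, y)} centred at coordinate \code{(x, y)} in pixel units.
#'
#' @slot pixels numeric matrix of intensities in [0, 255]; rows are image
#'   rows (y), columns are image columns (x).
#' @slot dpi numeric(1), scan resolution in dots per inch; > 0.
#'
#' @seealso [wspCard()], [pixelPitch()], [cardArea()], [binarize()]
#' @name WSPCard-class
#' @exportClass WSPCard
setClass("WSPCard", representation(pixels = "matrix", dpi = "numeric"))

setValidity("WSPCard", function(object) {
  msg <- character()
  if (length(object@dpi) != 1L || !is.finite(object@dpi) || object@dpi <= 0)
    msg <- c(msg, "'dpi' must be a single positive number")
  if (!is.numeric(object@pixels) || length(object@pixels) == 0L)
    msg <- c(msg, "'pixels' must be a non-empty numeric matrix")
  else if (min(object@pixels) < 0 || max(object@pixels) > 255)
    msg <- c(msg, "'pixels' intensities must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' Stain segmentation configuration
#'
#' @slot thresholdMode "automatic" (between-class-variance maximisation on
#'   the intensity histogram) or "fixed".
#' @slot fixedThreshold numeric(1) intensity in [0, 255]; used in fixed
#'   mode and as the fallback when automatic thresholding is impossible
#'   (uniform image).
#' @slot connectivity integer(1), 4 or 8 (default 8): pixel adjacency used
#'   for connected-component labelling.
#' @slot minPixels integer(1) >= 1: components smaller than this are
#'   discarded.
#' @slot stainsDarker logical(1): stains are the darker intensity class.
#'
#' @seealso [segmentationConfig()], [binarize()], [extractStains()]
#' @name SegmentationConfig-class
#' @exportClass SegmentationConfig
setClass("SegmentationConfig",
  representation(thresholdMode = "character", fixedThreshold = "numeric",
                 connectivity = "integer", minPixels = "integer",
                 stainsDarker = "logical"),
  prototype(thresholdMode = "automatic", fixedThreshold = 128,
            connectivity = 8L, minPixels = 1L, stainsDarker = TRUE))

setValidity("SegmentationConfig", function(object) {
  msg <- character()
  if (!object@thresholdMode %in% c("automatic", "fixed"))
    msg <- c(msg, "'thresholdMode' must be \"automatic\" or \"fixed\"")
  if (length(object@fixedThreshold) != 1L ||
      !is.finite(object@fixedThreshold) ||
      object@fixedThreshold < 0 || object@fixedThreshold > 255)
    msg <- c(msg, "'fixedThreshold' must be in [0, 255]")
  if (length(object@connectivity) != 1L ||
      !object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "'connectivity' must be 4 or 8")
  if (length(object@minPixels) != 1L || is.na(object@minPixels) ||
      object@minPixels < 1L)
    msg <- c(msg, "'minPixels' must be >= 1")
  if (length(object@stainsDarker) != 1L || is.na(object@stainsDarker))
    msg <- c(msg, "'stainsDarker' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Per-card spray metrics
#'
#' Summary of one WSP card: spray coverage (% of card surface stained),
#' spray density (stains per cm2), liquid deposition (sum of per-droplet
#' spherical volumes per cm2 of card, in uL cm-2) and, optionally, the
#' estimated active-ingredient residue (ug cm-2) once a tank-mix
#' concentration is applied. Cards whose coverage exceeds the exclusion
#' threshold (default 30%) are flagged: deposition estimates become
#' unreliable at high coverage because stains increasingly merge.
#'
#' @slot coveragePct numeric(1) in [0, 100].
#' @slot densityPerCm2 numeric(1), stains per cm2.
#' @slot depositionUlPerCm2 numeric(1), uL cm-2.
#' @slot residueUgPerCm2 numeric(1), ug cm-2 (NA until a tank mix is
#'   applied).
#' @slot nStains integer(1).
#' @slot cardAreaCm2 numeric(1), physical card area in cm2.
#' @slot highCoverageFlag logical(1), TRUE when coverage exceeds the
#'   threshold used at construction.
#'
#' @seealso [cardMetrics()], [coverage()], [deposition()],
#'   [dropletDensity()]
#' @name CardMetrics-class
#' @exportClass CardMetrics
setClass("CardMetrics",
  representation(coveragePct = "numeric", densityPerCm2 = "numeric",
                 depositionUlPerCm2 = "numeric", residueUgPerCm2 = "numeric",
                 nStains = "integer", cardAreaCm2 = "numeric",
                 highCoverageFlag = "logical"),
  prototype(residueUgPerCm2 = NA_real_))

setValidity("CardMetrics", function(object) {
  msg <- character()
  if (object@coveragePct < 0 || object@coveragePct > 100)
    msg <- c(msg, "'coveragePct' must lie in [0, 100]")
  if (object@densityPerCm2 < 0 || object@depositionUlPerCm2 < 0)
    msg <- c(msg, "density and deposition must be non-negative")
  if (object@nStains < 0L)
    msg <- c(msg, "'nStains' must be non-negative")
  if (object@cardAreaCm2 <= 0)
    msg <- c(msg, "'cardAreaCm2' must be positive")
  if (length(msg)) msg else TRUE
})

#' Empirical correction factor calibrating WSP residues to leaf residues
#'
#' WSP-derived residue estimates systematically overestimate the residue
#' measured analytically on leaves. The correction factor CF is the ratio
#' of arm means, CF = mean(leaf residues) / mean(WSP residues), both in
#' ug cm-2; corrected WSP residues are obtained by multiplying each WSP
#' value by CF.
#'
#' @slot cf numeric(1) > 0, the fitted correction factor.
#' @slot nLeaf,nWsp integer(1), number of samples per arm after
#'   exclusions.
#' @slot meanLeaf,meanWsp numeric(1), arm means in ug cm-2.
#' @slot nExcluded integer(1), WSP samples dropped by the coverage flag.
#'
#' @seealso [fitCorrectionFactor()], [applyCorrection()],
#'   [correctionFactor()]
#' @name CorrectionModel-class
#' @exportClass CorrectionModel
setClass("CorrectionModel",
  representation(cf = "numeric", nLeaf = "integer", nWsp = "integer",
                 meanLeaf = "numeric", meanWsp = "numeric",
                 nExcluded = "integer"),
  prototype(nExcluded = 0L))

setValidity("CorrectionModel", function(object) {
  msg <- character()
  if (length(object@cf) != 1L || !is.finite(object@cf) || object@cf <= 0)
    msg <- c(msg, "'cf' must be a single positive number")
  if (object@nLeaf < 1L || object@nWsp < 1L)
    msg <- c(msg, "both arms must contain at least one sample")
  if (length(msg)) msg else TRUE
})
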