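#' Droplet diameter from a stain under a spread-factor model
#'
#' Converts stain measurements to the diameter of the originating
#' droplet. The constant power-law model uses the stain area
#' (\eqn{d = SF \cdot A^{b}}); the binned model uses the equivalent-circle
#' stain diameter (\eqn{d = d_s / SF(d_s)}). Either \code{area} or
#' \code{stainDiameter} may be supplied: the one a model does not use
#' directly is derived through the equivalent-circle relation
#' \eqn{d_s = 2\sqrt{A/\pi}}.
#'
#' @param model a [SpreadFactorModel-class] object.
#' @param area numeric, stain area(s) in square micrometres.
#' @param stainDiameter numeric, equivalent-circle stain diameter(s) in
#'   micrometres.
#' @return numeric vector of droplet diameters in micrometres.
#' @examples
#' dropletDiameter(constantSpreadFactor(), area = pi * 50^2)   # 62.74 um
#' dropletDiameter(binnedSpreadFactor(), stainDiameter = 100)  # 58.82 um
#' @export
setGeneric("dropletDiameter",
  function(model, area = NULL, stainDiameter = NULL)
    standardGeneric("dropletDiameter"))

#' @rdname accessors
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))

#' @rdname accessors
#' @export
setGeneric("dropletDensity",
  function(object) standardGeneric("dropletDensity"))

#' @rdname accessors
#' @export
setGeneric("deposition", function(object) standardGeneric("deposition"))

#' @rdname accessors
#' @export
setGeneric("nStains", function(object) standardGeneric("nStains"))

#' @rdname accessors
#' @export
setGeneric("highCoverage", function(object) standardGeneric("highCoverage"))

#' @rdname accessors
#' @export
setGeneric("correctionFactor",
  function(object) standardGeneric("correctionFactor"))

#' @rdname wspCard
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @rdname wspCard
#' @export
setGeneric("cardArea", function(object) standardGeneric("cardArea"))
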