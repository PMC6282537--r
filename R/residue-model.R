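#' Residue per unit leaf area
#'
#' Converts a whole-leaf residue mass to an areal residue, assuming the
#' entire residue sits on the upper leaf surface:
#' \eqn{R_{area} = R_{leaf} / A} with \eqn{R_{leaf}} in ug and \eqn{A}
#' the upper-surface leaf area in cm2.
#'
#' @param residueUg residue mass per leaf in micrograms; >= 0.
#' @param leafAreaCm2 upper-surface leaf area in cm2; > 0.
#' @return numeric, residue in ug cm-2.
#' @examples
#' residuePerArea(2, 20)  # 0.1 ug cm-2
#' @export
residuePerArea <- function(residueUg, leafAreaCm2) {
  if (any(!is.finite(leafAreaCm2)) || any(leafAreaCm2 <= 0))
    stop("leaf areas must be positive and finite")
  if (any(!is.finite(residueUg)) || any(residueUg < 0))
    stop("residues must be non-negative and finite")
  residueUg / leafAreaCm2
}

#' Residue estimated from card deposition and tank-mix concentration
#'
#' \eqn{R = C \times D}: the active-ingredient residue deposited per unit
#' area equals the tank-mix concentration (ug of active ingredient per uL
#' of spray solution) times the liquid deposition measured on the card
#' (uL cm-2).
#'
#' @param concentration tank-mix active-ingredient concentration in
#'   ug uL-1; >= 0.
#' @param deposition liquid deposition in uL cm-2; >= 0.
#' @return numeric, residue in ug cm-2.
#' @examples
#' depositFromDeposition(0.18, 1.0)  # 0.18 ug cm-2
#' @export
depositFromDeposition <- function(concentration, deposition) {
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("'concentration' must be non-negative and finite")
  if (any(!is.finite(deposition)) || any(deposition < 0))
    stop("deposition must be non-negative and finite")
  concentration * deposition
}

#' Derive per-leaf residue quantities
#'
#' Appends \code{residue_mg_per_kg} (= ug residue / g leaf mass) and
#' \code{residue_ug_per_cm2} (= ug residue / cm2 upper leaf surface) to a
#' leaf residue table.
#'
#' @param leaves data.frame with columns \code{mass_g}, \code{area_cm2},
#'   \code{residue_ug}.
#' @return the table with the derived columns appended.
#' @export
leafResidueTable <- function(leaves) {
  stopifnot(is.data.frame(leaves),
            all(c("mass_g", "area_cm2", "residue_ug") %in% names(leaves)))
  if (any(leaves$mass_g <= 0)) stop("leaf masses must be positive")
  leaves$residue_mg_per_kg <- leaves$residue_ug / leaves$mass_g
  leaves$residue_ug_per_cm2 <- residuePerArea(leaves$residue_ug,
                                              leaves$area_cm2)
  leaves
}

#' Fit the empirical correction factor
#'
#' The correction factor is the ratio of arm means,
#' \eqn{CF = \bar{R}_{leaf} / \bar{R}_{WSP}}, computed after removing WSP
#' samples flagged for high coverage (stains merge above ~30% coverage
#' and volume estimates become unreliable). A ratio of means — rather
#' than a mean of per-pair ratios or a regression slope — is used because
#' the two arms are unpaired samples of different sizes from different
#' substrates, and the ratio of means is the factor that makes the
#' corrected WSP mean equal the leaf mean exactly.
#'
#' @param leafResidues numeric vector of leaf residues, ug cm-2.
#' @param wspResidues numeric vector of WSP-derived residues, ug cm-2.
#' @param excludeWsp optional logical vector along \code{wspResidues};
#'   TRUE marks samples to drop (e.g. high-coverage flags).
#' @return a [CorrectionModel-class] object.
#' @examples
#' m <- fitCorrectionFactor(0.039, 0.24)
#' correctionFactor(m)               # 0.1625
#' applyCorrection(0.24, m)          # 0.039
#' @export
fitCorrectionFactor <- function(leafResidues, wspResidues,
                                excludeWsp = NULL) {
  if (!is.null(excludeWsp)) {
    stopifnot(length(excludeWsp) == length(wspResidues))
    wspKept <- wspResidues[!excludeWsp]
  } else {
    wspKept <- wspResidues
  }
  if (length(leafResidues) == 0L)
    stop("leaf arm is empty")
  if (length(wspKept) == 0L)
    stop("WSP arm is empty after exclusions")
  mw <- mean(wspKept)
  if (mw == 0) stop("WSP arm mean is zero; correction factor undefined")
  new("CorrectionModel",
      cf = mean(leafResidues) / mw,
      nLeaf = length(leafResidues), nWsp = length(wspKept),
      meanLeaf = mean(leafResidues), meanWsp = mw,
      nExcluded = length(wspResidues) - length(wspKept))
}

#' @rdname accessors
setMethod("correctionFactor", "CorrectionModel", function(object) object@cf)

#' Apply a fitted correction factor to WSP residues
#'
#' \eqn{R_{corrected} = R \times CF}, applied per data point.
#'
#' @param wspResidue numeric, WSP-derived residue(s) in ug cm-2; >= 0.
#' @param model a [CorrectionModel-class] object.
#' @return numeric, corrected residue(s) in ug cm-2.
#' @export
applyCorrection <- function(wspResidue, model) {
  stopifnot(is(model, "CorrectionModel"))
  if (any(!is.finite(wspResidue)) || any(wspResidue < 0))
    stop("WSP residues must be non-negative and finite")
  wspResidue * model@cf
}

setMethod("show", "CorrectionModel", function(object) {
  cat("CorrectionModel\n")
  cat(sprintf("  CF = %.4f (leaf mean %.4g / WSP mean %.4g ug cm-2)\n",
              object@cf, object@meanLeaf, object@meanWsp))
  cat(sprintf("  n = %d leaf, %d WSP (%d WSP excluded)\n",
              object@nLeaf, object@nWsp, object@nExcluded))
})

lnParams <- function(cv) {
  # lognormal sdlog for a target coefficient of variation
  sqrt(log(1 + cv^2))
}

#' Simulate paired leaf and WSP residue arms
#'
#' Generates synthetic calibration data in which both arms observe the
#' same latent spray-deposit field. Deposits vary across sampling
#' locations (shared lognormal spatial variation); the leaf arm measures
#' \eqn{\gamma} times the deposit with its own multiplicative measurement
#' noise, the WSP arm measures the deposit with its own noise. The shared
#' spatial component has CV equal to the smaller of the two target arm
#' CVs and each arm's residual noise makes up its marginal CV, so the
#' generated arms reproduce the requested marginal CVs while remaining
#' positively dependent through the field they both sample.
#'
#' @param gamma true leaf/WSP ratio (the correction factor to recover).
#' @param nLeaf,nWsp samples per arm (defaults 90 and 61, the calibration
#'   sample sizes of the motivating field study).
#' @param meanLeaf leaf-arm mean residue, ug cm-2 (default 0.039).
#' @param cvLeaf,cvWsp marginal coefficient of variation per arm
#'   (defaults 0.50 and 0.44).
#' @param seed optional integer seed.
#' @return list with numeric vectors \code{leaf} and \code{wsp}
#'   (ug cm-2) and the generating parameters.
#' @examples
#' sim <- simulatePairedResidues(0.1625, seed = 1)
#' correctionFactor(fitCorrectionFactor(sim$leaf, sim$wsp))
#' @export
simulatePairedResidues <- function(gamma, nLeaf = 90, nWsp = 61,
                                   meanLeaf = 0.039,
                                   cvLeaf = 0.50, cvWsp = 0.44,
                                   seed = NULL) {
  stopifnot(gamma > 0, nLeaf >= 1, nWsp >= 1, meanLeaf > 0,
            cvLeaf >= 0, cvWsp >= 0)
  if (!is.null(seed)) set.seed(seed)
  sShared <- lnParams(min(cvLeaf, cvWsp))
  sLeafTot <- lnParams(cvLeaf)
  sWspTot <- lnParams(cvWsp)
  sLeaf <- sqrt(max(sLeafTot^2 - sShared^2, 0))
  sWsp <- sqrt(max(sWspTot^2 - sShared^2, 0))
  nLoc <- max(nLeaf, nWsp)
  z <- rnorm(nLoc, -sShared^2 / 2, sShared)      # shared spatial field
  leaf <- meanLeaf *
    exp(z[seq_len(nLeaf)] + rnorm(nLeaf, -sLeaf^2 / 2, sLeaf))
  wsp <- (meanLeaf / gamma) *
    exp(z[seq_len(nWsp)] + rnorm(nWsp, -sWsp^2 / 2, sWsp))
  list(leaf = leaf, wsp = wsp, gamma = gamma,
       nLeaf = nLeaf, nWsp = nWsp, meanLeaf = meanLeaf,
       cvLeaf = cvLeaf, cvWsp = cvWsp)
}
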