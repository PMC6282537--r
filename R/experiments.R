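#' Sample a right-skewed set of stain diameters
#'
#' Log-uniform sample over a diameter range, reproducing the strong
#' right skew of field droplet spectra (most droplets small, a long tail
#' of large ones). The default range covers the span used in the
#' artificial-stain validation experiments, 95.5-1438 um.
#'
#' @param n number of diameters (default 33).
#' @param range length-2 numeric, diameter range in um.
#' @param seed optional integer seed.
#' @return numeric vector of diameters in um.
#' @export
sampleStainDiameters <- function(n = 33, range = c(95.5, 1438),
                                 seed = NULL) {
  stopifnot(n >= 1, length(range) == 2L, range[1] > 0,
            range[2] > range[1])
  if (!is.null(seed)) set.seed(seed)
  exp(runif(n, log(range[1]), log(range[2])))
}

# rasterize one stain per minimal canvas and measure it back
measureRasterizedStains <- function(diameters, dpi,
                                    config = segmentationConfig()) {
  pitch <- 25400 / dpi
  vapply(diameters, function(d) {
    side <- max(ceiling(d / pitch) + 9L, 12L)
    mid <- (side - 1) / 2
    card <- rasterizeCircle(blankCard(side, side, dpi = dpi), mid, mid, d)
    st <- extractStains(binarize(card, config), dpi, config)
    if (nrow(st) != 1L)
      stop("expected one stain for a single rasterized circle, got ",
           nrow(st))
    st$area_um2
  }, 0)
}

#' Spread-factor comparison experiment
#'
#' For each stain diameter, computes the droplet diameter and spherical
#' volume under both the constant power-law and the diameter-binned
#' spread-factor model, and tabulates the percent difference. In
#' \code{"analytic"} mode stain areas are exact circle areas
#' \eqn{\pi (d/2)^2}; in \code{"rasterized"} mode each stain is drawn on
#' a synthetic card at the given dpi, segmented, and its measured area
#' used — quantifying what pixelation adds on top of the model
#' disagreement.
#'
#' @param stainDiameters numeric vector of stain diameters in um.
#' @param mode "analytic" or "rasterized".
#' @param dpi scan resolution for rasterized mode.
#' @param constantModel,binnedModel the two spread-factor models.
#' @param nBoot bootstrap replicates for the CI on the mean volume ratio
#'   (0 disables).
#' @param seed integer seed (bootstrap resampling).
#' @return an object of class \code{spreadFactorComparison}: list with
#'   \code{table} (per-stain rows: input and measured stain diameter,
#'   area, both droplet diameters, percent difference rounded to 2 dp,
#'   both volumes), \code{summary} (mean volumes, mean percent
#'   difference, percent by which the constant-model mean volume exceeds
#'   the binned one, deposition ranges, bootstrap CI) and \code{config}.
#' @examples
#' rep <- runSpreadFactorComparison(c(100, 200, 300, 400, 500, 600))
#' rep$table$d_constant_um  # 62.74 117.90 170.51 221.54 271.42 320.40
#' @export
runSpreadFactorComparison <- function(stainDiameters,
                                      mode = c("analytic", "rasterized"),
                                      dpi = 600,
                                      constantModel = constantSpreadFactor(),
                                      binnedModel = binnedSpreadFactor(),
                                      nBoot = 1000, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(stainDiameters > 0))
  if (mode == "analytic") {
    area <- pi * (stainDiameters / 2)^2
  } else {
    area <- measureRasterizedStains(stainDiameters, dpi)
  }
  dsMeasured <- stainDiameterFromArea(area)
  dConst <- dropletDiameter(constantModel, area = area)
  dBinned <- dropletDiameter(binnedModel, stainDiameter = dsMeasured)
  volConst <- dropletVolume(dConst)
  volBinned <- dropletVolume(dBinned)
  tab <- data.frame(stain_diameter_um = stainDiameters,
                    measured_stain_diameter_um = dsMeasured,
                    area_um2 = area,
                    d_constant_um = dConst,
                    d_binned_um = dBinned,
                    pct_difference = round(percentDifference(dConst,
                                                             dBinned), 2),
                    vol_constant_uL = volConst,
                    vol_binned_uL = volBinned)
  summ <- list(n = length(stainDiameters),
               mean_vol_constant_uL = mean(volConst),
               mean_vol_binned_uL = mean(volBinned),
               mean_pct_difference = mean(percentDifference(dConst,
                                                            dBinned)),
               pct_mean_vol_higher =
                 100 * (mean(volConst) / mean(volBinned) - 1),
               range_constant_uL = range(volConst),
               range_binned_uL = range(volBinned))
  if (nBoot > 0 && length(volConst) > 1) {
    set.seed(seed)
    ratios <- vapply(seq_len(nBoot), function(i) {
      j <- sample.int(length(volConst), replace = TRUE)
      100 * (mean(volConst[j]) / mean(volBinned[j]) - 1)
    }, 0)
    summ$pct_mean_vol_higher_ci95 <-
      unname(quantile(ratios, c(0.025, 0.975)))
  }
  structure(list(table = tab, summary = summ,
                 config = list(mode = mode, dpi = dpi, seed = seed,
                               nBoot = nBoot,
                               constantModel = constantModel,
                               binnedModel = binnedModel)),
            class = "spreadFactorComparison")
}

#' @export
print.spreadFactorComparison <- function(x, ...) {
  cat("Spread-factor comparison (", x$config$mode, " areas, n = ",
      x$summary$n, ")\n", sep = "")
  print(cbind(x$table[, c("stain_diameter_um", "d_constant_um",
                          "d_binned_um", "pct_difference")]),
        row.names = FALSE, digits = 5)
  cat(sprintf("mean volume: constant %.4g uL, binned %.4g uL (+%.1f%%)\n",
              x$summary$mean_vol_constant_uL,
              x$summary$mean_vol_binned_uL,
              x$summary$pct_mean_vol_higher))
  invisible(x)
}

#' Touching-droplet experiment
#'
#' Quantifies the deposition overestimate caused by treating two tangent
#' stains as one merged deposit. For each diameter the experiment builds
#' an image pair — two equal stains separated, and the same two stains
#' tangent — and compares per-image deposition (summed stain volumes).
#' In \code{"analytic"} mode the merged stain is a single stain of twice
#' the area, for which the constant power-law model gives a closed-form
#' overestimate of \eqn{2^{3b-1} - 1} (28.79% at b = 0.455),
#' independent of diameter. In \code{"rasterized"} mode images are drawn
#' and segmented, so pixelation perturbs the measured areas.
#'
#' @param stainDiameters numeric vector of stain diameters in um.
#' @param mode "rasterized" or "analytic".
#' @param dpi scan resolution for rasterized mode.
#' @param model spread-factor model used for volumes (constant power-law
#'   by default, matching deposit-scanning software).
#' @param seed integer seed (recorded; the experiment itself is
#'   deterministic).
#' @return object of class \code{touchingTest}: list with \code{table}
#'   (per diameter: touching and separated deposition in uL per image,
#'   component counts, overestimation %), \code{summary} (mean
#'   overestimation %) and \code{config}.
#' @examples
#' rt <- runTouchingTest(c(200, 400), mode = "analytic")
#' rt$table$overestimation_pct  # both 28.79 (= 100 * (2^0.365 - 1))
#' @export
runTouchingTest <- function(stainDiameters,
                            mode = c("rasterized", "analytic"),
                            dpi = 600,
                            model = constantSpreadFactor(),
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(stainDiameters > 0))
  config <- segmentationConfig()
  rows <- lapply(stainDiameters, function(d) {
    if (mode == "analytic") {
      a <- pi * (d / 2)^2
      volSep <- 2 * dropletVolume(dropletDiameter(model, area = a))
      volTouch <- dropletVolume(dropletDiameter(model, area = 2 * a))
      nSep <- 2L; nTouch <- 1L
    } else {
      pitch <- 25400 / dpi
      dPx <- d / pitch
      w <- ceiling(2 * dPx) + 16L
      h <- ceiling(dPx) + 12L
      depo <- function(touching) {
        pair <- generateTouchingPair(d, w, h, dpi = dpi,
                                     touching = touching)
        st <- extractStains(binarize(pair$card, config), dpi, config)
        st <- addDropletEstimates(st, model)
        list(vol = sum(st$volume_uL), n = nrow(st))
      }
      sep <- depo(FALSE); tou <- depo(TRUE)
      volSep <- sep$vol; volTouch <- tou$vol
      nSep <- sep$n; nTouch <- tou$n
    }
    data.frame(stain_diameter_um = d,
               vol_touching_uL = volTouch,
               vol_separated_uL = volSep,
               n_components_touching = nTouch,
               n_components_separated = nSep,
               overestimation_pct = 100 * (volTouch - volSep) / volSep)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 summary = list(
                   n = nrow(tab),
                   mean_overestimation_pct = mean(tab$overestimation_pct),
                   mean_vol_touching_uL = mean(tab$vol_touching_uL),
                   mean_vol_separated_uL = mean(tab$vol_separated_uL)),
                 config = list(mode = mode, dpi = dpi, seed = seed,
                               model = model)),
            class = "touchingTest")
}

#' @export
print.touchingTest <- function(x, ...) {
  cat("Touching-droplet test (", x$config$mode, ", n = ",
      x$summary$n, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("mean overestimation when touching: %.1f%%\n",
              x$summary$mean_overestimation_pct))
  invisible(x)
}

#' Compare leaf-measured and WSP-estimated residues
#'
#' The method-comparison analysis: WSP cards above the coverage
#' threshold are excluded, retained card depositions are converted to
#' residues through the tank-mix concentration, a correction factor is
#' fitted as the ratio of arm means, and per-point corrected WSP
#' residues are reported alongside before/after summaries and the
#' ratio of uncorrected means.
#'
#' @param leafResidues numeric vector of leaf residues (ug cm-2), or a
#'   leaf table with columns \code{mass_g}, \code{area_cm2},
#'   \code{residue_ug} (converted via [leafResidueTable()]).
#' @param cards card summary data.frame with \code{coverage_pct} and
#'   \code{deposition_uL_per_cm2} columns.
#' @param concentration tank-mix concentration, ug uL-1.
#' @param coverageThreshold exclusion threshold, % (default 30).
#' @return object of class \code{methodComparison}: list with
#'   \code{correction} (a [CorrectionModel-class]), \code{leaf_summary},
#'   \code{wsp_summary}, \code{corrected_summary} (from
#'   [groupSummary()]), \code{ratio_uncorrected} (WSP mean / leaf mean),
#'   \code{wsp_residues}, \code{corrected_residues}, and the exclusion
#'   \code{report}.
#' @export
compareMethods <- function(leafResidues, cards, concentration,
                           coverageThreshold = 30) {
  if (is.data.frame(leafResidues)) {
    leafResidues <- leafResidueTable(leafResidues)$residue_ug_per_cm2
  }
  stopifnot(is.numeric(leafResidues), length(leafResidues) > 0,
            is.data.frame(cards),
            all(c("coverage_pct", "deposition_uL_per_cm2") %in%
                names(cards)))
  filt <- exclusionFilter(cards, coverageThreshold)
  if (nrow(filt$retained) == 0L)
    stop("no WSP cards remain after the coverage exclusion")
  wsp <- depositFromDeposition(concentration,
                               filt$retained$deposition_uL_per_cm2)
  model <- fitCorrectionFactor(leafResidues, wsp)
  corrected <- applyCorrection(wsp, model)
  structure(list(correction = model,
                 leaf_summary = groupSummary(leafResidues),
                 wsp_summary = groupSummary(wsp),
                 corrected_summary = groupSummary(corrected),
                 ratio_uncorrected = mean(wsp) / mean(leafResidues),
                 wsp_residues = wsp,
                 corrected_residues = corrected,
                 exclusion = filt$report),
            class = "methodComparison")
}

#' @export
print.methodComparison <- function(x, ...) {
  cat("Method comparison: leaf residues vs WSP-derived residues\n")
  cat(sprintf("  WSP cards: %d used, %d excluded (coverage > %g%%)\n",
              x$correction@nWsp, x$exclusion$n_excluded,
              x$exclusion$threshold))
  cat(sprintf("  leaf mean  %.4g ug cm-2 (n = %d)\n",
              x$leaf_summary$mean, x$leaf_summary$n))
  cat(sprintf("  WSP mean   %.4g ug cm-2 (n = %d), %.2fx the leaf mean\n",
              x$wsp_summary$mean, x$wsp_summary$n, x$ratio_uncorrected))
  cat(sprintf("  CF = %.4f; corrected WSP mean %.4g ug cm-2\n",
              correctionFactor(x$correction), x$corrected_summary$mean))
  invisible(x)
}
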