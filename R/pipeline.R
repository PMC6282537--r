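#' Analyse WSP cards end to end
#'
#' Full card-to-report pipeline: binarize each card, extract stains,
#' apply the configured spread-factor model, compute per-card metrics
#' and — when a tank-mix concentration is configured — estimate the
#' active-ingredient residue (with the configured correction factor
#' applied, if any). Inputs may be image paths (read at the configured
#' dpi) or [WSPCard-class] objects. The pipeline is deterministic:
#' identical inputs and configuration give identical outputs.
#'
#' @param cards character vector of image paths, a [WSPCard-class], or a
#'   list of [WSPCard-class] objects.
#' @param config configuration list (see [defaultRunConfig()]).
#' @param cardIds optional card identifiers (default: file names or
#'   card001, card002, ...).
#' @return list with \code{cards} (card summary table: card_id,
#'   coverage_pct, density_per_cm2, deposition_uL_per_cm2, n_stains,
#'   high_coverage_flag and, when a concentration is set,
#'   residue_ug_per_cm2) and \code{stains} (stain table with a card_id
#'   column). Unreadable images are skipped with a warning; if every
#'   input fails the pipeline stops.
#' @examples
#' gen <- generateCard(c(300, 500), 120, 120, dpi = 600, seed = 7)
#' analyzeCards(gen$card)$cards
#' @export
analyzeCards <- function(cards, config = defaultRunConfig(),
                         cardIds = NULL) {
  validateConfig(config)
  if (is(cards, "WSPCard")) cards <- list(cards)
  if (is.character(cards)) {
    paths <- cards
    if (is.null(cardIds))
      cardIds <- tools::file_path_sans_ext(basename(paths))
    cards <- lapply(paths, function(p) {
      tryCatch(readCardImage(p, dpi = config$dpi),
               error = function(e) {
                 warning("skipping unreadable image ", p, ": ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               })
    })
    ok <- !vapply(cards, is.null, TRUE)
    if (!any(ok)) stop("no readable card images")
    cards <- cards[ok]
    cardIds <- cardIds[ok]
  }
  if (is.null(cardIds)) cardIds <- sprintf("card%03d", seq_along(cards))
  model <- spreadFactorModelFromConfig(config)
  segcfg <- segmentationConfigFromConfig(config)
  stainTabs <- vector("list", length(cards))
  metrics <- vector("list", length(cards))
  for (i in seq_along(cards)) {
    card <- cards[[i]]
    stopifnot(is(card, "WSPCard"))
    mask <- binarize(card, segcfg)
    st <- extractStains(mask, card@dpi, segcfg)
    st <- addDropletEstimates(st, model)
    m <- cardMetrics(st, cardAreaCm2 = cardArea(card),
                     stainedPixels = sum(mask),
                     totalPixels = length(mask),
                     model = model,
                     coverageThreshold = config$coverage_threshold)
    if (!is.null(config$tank_concentration) &&
        config$tank_concentration > 0) {
      res <- depositFromDeposition(config$tank_concentration,
                                   deposition(m))
      if (!is.null(config$correction_factor))
        res <- res * config$correction_factor
      m@residueUgPerCm2 <- res
    }
    metrics[[i]] <- m
    if (nrow(st))
      st <- cbind(card_id = cardIds[i], st, stringsAsFactors = FALSE)
    stainTabs[[i]] <- st
  }
  stains <- do.call(rbind, stainTabs[vapply(stainTabs, nrow, 0L) > 0])
  if (is.null(stains))
    stains <- cbind(data.frame(card_id = character(0)),
                    addDropletEstimates(extractStains(
                      matrix(FALSE, 1, 1), config$dpi, segcfg), model))
  rownames(stains) <- NULL
  list(cards = cardSummaryTable(metrics, cardIds), stains = stains)
}

#' Read and write the tabular interchange formats
#'
#' @description
#' Stain tables (\code{stain_id}, \code{pixel_count}, \code{area_um2},
#' \code{stain_diameter_um}, \code{droplet_diameter_um},
#' \code{volume_uL}), card summaries (\code{card_id},
#' \code{coverage_pct}, \code{density_per_cm2},
#' \code{deposition_uL_per_cm2}, \code{n_stains},
#' \code{high_coverage_flag}) and leaf tables (\code{leaf_id},
#' \code{patch}, \code{tree}, \code{zone}, \code{mass_g},
#' \code{area_cm2}, \code{residue_ug}) are exchanged as plain CSV with a
#' header row.
#'
#' @param x data.frame to write.
#' @param path CSV file path.
#' @param required character vector of columns that must be present when
#'   reading.
#' @return readers return the data.frame; writers return the path,
#'   invisibly.
#' @name wspCSV
#' @export
writeWspCsv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname wspCSV
#' @export
readWspCsv <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  x
}
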