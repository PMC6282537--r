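#' Run configuration
#'
#' @description
#' `defaultRunConfig()` returns the default pipeline configuration as a
#' named list: 600 dpi scans, the constant power-law spread factor
#' (SF 1.06, exponent 0.455), automatic thresholding with 8-connectivity
#' segmentation, a 30% coverage-exclusion threshold and a tank-mix
#' concentration of 0.18 ug uL-1 (the example study's penconazole
#' mixture). `validateConfig()` checks ranges and returns the config
#' invisibly or stops with a named validation error. `loadConfig()` /
#' `saveConfig()` read and write the configuration as YAML; a saved
#' config reloads identically.
#'
#' @param config a configuration list.
#' @param path file path for YAML load/save.
#' @return a validated configuration list.
#' @examples
#' cfg <- defaultRunConfig()
#' cfg$dpi
#' @export
defaultRunConfig <- function() {
  list(
    dpi = 600,
    spread_factor = list(kind = "constant_powerlaw",
                         sf = 1.06, exponent = 0.455,
                         bin_upper = c(100, 200, 300, 400, 500, 600),
                         bin_factors = c(1.7, 1.8, 1.9, 2.0, 2.1, 2.1)),
    segmentation = list(threshold_mode = "automatic",
                        fixed_threshold = 128,
                        connectivity = 8,
                        min_pixels = 1,
                        stains_darker = TRUE),
    tank_concentration = 0.18,
    coverage_threshold = 30,
    correction_factor = NULL,
    seed = 1
  )
}

#' @rdname defaultRunConfig
#' @export
validateConfig <- function(config) {
  fail <- function(field, why)
    stop("invalid config field '", field, "': ", why, call. = FALSE)
  num1 <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  if (!num1(config$dpi) || config$dpi <= 0)
    fail("dpi", "must be a positive number")
  sf <- config$spread_factor
  if (!sf$kind %in% c("constant_powerlaw", "binned"))
    fail("spread_factor$kind",
         "must be \"constant_powerlaw\" or \"binned\"")
  if (!num1(sf$sf) || sf$sf <= 0)
    fail("spread_factor$sf", "must be a positive number")
  if (!num1(sf$exponent) || sf$exponent <= 0 || sf$exponent >= 1)
    fail("spread_factor$exponent", "must lie in (0, 1)")
  if (length(sf$bin_upper) != length(sf$bin_factors) ||
      any(diff(sf$bin_upper) <= 0) || any(sf$bin_factors < 1))
    fail("spread_factor$bin_upper/bin_factors",
         "bounds must increase strictly and factors be >= 1")
  seg <- config$segmentation
  if (!seg$threshold_mode %in% c("automatic", "fixed"))
    fail("segmentation$threshold_mode",
         "must be \"automatic\" or \"fixed\"")
  if (!num1(seg$fixed_threshold) || seg$fixed_threshold < 0 ||
      seg$fixed_threshold > 255)
    fail("segmentation$fixed_threshold", "must lie in [0, 255]")
  if (!num1(seg$connectivity) || !seg$connectivity %in% c(4, 8))
    fail("segmentation$connectivity", "must be 4 or 8")
  if (!num1(seg$min_pixels) || seg$min_pixels < 1)
    fail("segmentation$min_pixels", "must be >= 1")
  if (!is.logical(seg$stains_darker) || length(seg$stains_darker) != 1L)
    fail("segmentation$stains_darker", "must be TRUE or FALSE")
  if (!num1(config$tank_concentration) || config$tank_concentration < 0)
    fail("tank_concentration", "must be >= 0")
  if (!num1(config$coverage_threshold) ||
      config$coverage_threshold <= 0 || config$coverage_threshold > 100)
    fail("coverage_threshold", "must lie in (0, 100]")
  if (!is.null(config$correction_factor) &&
      (!num1(config$correction_factor) || config$correction_factor <= 0))
    fail("correction_factor", "must be NULL or a positive number")
  if (!num1(config$seed))
    fail("seed", "must be a number")
  invisible(config)
}

#' @rdname defaultRunConfig
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(defaultRunConfig(), user)
  # modifyList drops NULL-valued entries; correction_factor = NULL is a
  # meaningful setting (no fixed correction), so keep the element
  if (!"correction_factor" %in% names(config))
    config["correction_factor"] <- list(NULL)
  config <- config[names(defaultRunConfig())]
  validateConfig(config)
  config
}

#' @rdname defaultRunConfig
#' @export
saveConfig <- function(config, path) {
  validateConfig(config)
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Build objects from a configuration
#'
#' @description
#' `spreadFactorModelFromConfig()` and
#' `segmentationConfigFromConfig()` turn the corresponding config
#' sections into the S4 objects the pipeline consumes.
#'
#' @param config a validated configuration list.
#' @return a [SpreadFactorModel-class] or [SegmentationConfig-class].
#' @export
spreadFactorModelFromConfig <- function(config) {
  sf <- config$spread_factor
  if (sf$kind == "constant_powerlaw")
    constantSpreadFactor(sf = sf$sf, exponent = sf$exponent)
  else
    binnedSpreadFactor(upper = sf$bin_upper, factors = sf$bin_factors)
}

#' @rdname spreadFactorModelFromConfig
#' @export
segmentationConfigFromConfig <- function(config) {
  seg <- config$segmentation
  segmentationConfig(thresholdMode = seg$threshold_mode,
                     fixedThreshold = seg$fixed_threshold,
                     connectivity = seg$connectivity,
                     minPixels = seg$min_pixels,
                     stainsDarker = seg$stains_darker)
}
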