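#' Grouped descriptive summaries (mean, 95% CI, CV)
#'
#' Per-group sample size, mean, t-based 95% confidence interval
#' (mean +- t[0.975, n-1] * sd / sqrt(n)) and coefficient of variation
#' (100 * sd / mean). The t distribution is used rather than the normal
#' because per-group sample sizes in nested field designs are often
#' small. Groups with fewer than two observations get an undefined CI
#' (flagged, not an error).
#'
#' @param values numeric vector of observations.
#' @param groups optional grouping vector (same length); omitted means
#'   one overall group.
#' @return data.frame with columns \code{group}, \code{n}, \code{mean},
#'   \code{ci95_lower}, \code{ci95_upper}, \code{cv_pct},
#'   \code{ci_defined}.
#' @examples
#' groupSummary(c(1, 2, 3))  # mean 2, CV 50, CI 2 +- 4.303/sqrt(3)
#' @export
groupSummary <- function(values, groups = NULL) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (is.null(groups)) groups <- rep("all", length(values))
  stopifnot(length(groups) == length(values))
  out <- lapply(split(values, groups), function(v) {
    n <- length(v)
    m <- mean(v)
    if (n >= 2L) {
      s <- sd(v)
      half <- qt(0.975, n - 1) * s / sqrt(n)
      data.frame(n = n, mean = m, ci95_lower = m - half,
                 ci95_upper = m + half,
                 cv_pct = if (m != 0) 100 * s / m else NA_real_,
                 ci_defined = TRUE)
    } else {
      data.frame(n = n, mean = m, ci95_lower = NA_real_,
                 ci95_upper = NA_real_, cv_pct = NA_real_,
                 ci_defined = FALSE)
    }
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = names(out), stringsAsFactors = FALSE),
               res)
  rownames(res) <- NULL
  res
}

#' Welch two-sample comparison
#'
#' Unequal-variances t-test (Welch's t-test with Welch-Satterthwaite
#' degrees of freedom) comparing two groups; reports the mean difference
#' (a - b), its 95% CI and the two-sided p-value. If both groups have
#' zero variance the test statistic is undefined and an exact-equality
#' shortcut is used: p = 1 when the group means are equal, p = 0
#' otherwise, with a zero-width CI.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with \code{mean_diff}, \code{ci95_lower},
#'   \code{ci95_upper}, \code{p_value}, \code{df}, \code{statistic}.
#' @export
welchCompare <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  d <- mean(a) - mean(b)
  if (var(a) == 0 && var(b) == 0) {
    return(list(mean_diff = d, ci95_lower = d, ci95_upper = d,
                p_value = if (d == 0) 1 else 0,
                df = NA_real_, statistic = NA_real_))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(mean_diff = d,
       ci95_lower = unname(tt$conf.int[1]),
       ci95_upper = unname(tt$conf.int[2]),
       p_value = tt$p.value,
       df = unname(tt$parameter),
       statistic = unname(tt$statistic))
}

#' Exclude high-coverage cards
#'
#' Retains cards whose coverage does not exceed the threshold (default
#' 30%): above that point stains merge extensively and deposition
#' estimates are unreliable, so such cards are omitted from residue
#' calibration.
#'
#' @param cards data.frame with a \code{coverage_pct} column (card
#'   summary table layout).
#' @param threshold coverage percentage in (0, 100].
#' @return list with \code{retained} and \code{excluded} data.frames and
#'   a \code{report} (counts, fraction excluded, threshold). Applying the
#'   filter twice changes nothing (idempotent).
#' @export
exclusionFilter <- function(cards, threshold = 30) {
  stopifnot(is.data.frame(cards), "coverage_pct" %in% names(cards),
            length(threshold) == 1L, threshold > 0, threshold <= 100)
  keep <- cards$coverage_pct <= threshold
  list(retained = cards[keep, , drop = FALSE],
       excluded = cards[!keep, , drop = FALSE],
       report = list(n_total = nrow(cards),
                     n_excluded = sum(!keep),
                     fraction_excluded =
                       if (nrow(cards)) sum(!keep) / nrow(cards) else 0,
                     threshold = threshold))
}
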