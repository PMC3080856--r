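# Detection-power extrapolation: decile histogram of relative expression
# changes among DE genes, linear projection of the under-ascertained first
# decile, and the implied count of genes escaping detection.

DECILE_LABELS <- c("0-10", "10-20", "20-30", "30-40", "40-50", "50+")

#' Decile histogram of relative expression changes among DE genes
#'
#' Converts each DE gene's log2 fold-change to a relative change
#' `(2^|log_fc| - 1) * 100%` and bins into half-open 10-percentage-point
#' bins `[0,10), [10,20), ..., [40,50), [50,Inf)`.
#'
#' @param results ContrastResult data.frame.
#' @param p_cut raw p-value threshold defining the DE genes.
#' @return Named integer vector of six bin counts.
#' @export
decile_histogram <- function(results, p_cut) {
  check_number(p_cut, "p_cut", lower = 0, upper = 1, strict_lower = TRUE)
  if (nrow(results) == 0) stop_bad_arg("empty results")
  de <- results$tested & !is.na(results$p) & results$p < p_cut
  pct <- (2^abs(results$log_fc[de]) - 1) * 100
  bins <- findInterval(pct, c(0, 10, 20, 30, 40, 50))
  counts <- tabulate(bins, nbins = 6)
  names(counts) <- DECILE_LABELS
  counts
}

#' Project the first decile from the next four
#'
#' Ordinary least squares of the counts in the 10-20, 20-30, 30-40 and
#' 40-50 percent bins on the bin index (x = 2..5), evaluated at x = 1. A
#' negative projection is clamped to zero and flagged: an increasing count
#' profile carries no evidence of under-ascertainment.
#'
#' @param counts numeric vector of exactly four counts for the bins
#'   10-20 ... 40-50, in order.
#' @return list of class `decile_projection`: `slope`, `intercept`,
#'   `projected_first_decile`, `clamped`.
#' @export
project_first_decile <- function(counts) {
  if (length(counts) != 4 || any(!is.finite(counts)) || any(counts < 0)) {
    stop_bad_arg("`counts` must be four non-negative finite numbers")
  }
  x <- 2:5
  slope <- stats::cov(x, counts) / stats::var(x)
  intercept <- mean(counts) - slope * mean(x)
  proj <- intercept + slope * 1
  # a non-positive projection can only arise from an increasing profile,
  # which carries no evidence of under-ascertainment
  clamped <- proj <= 0 && slope > 0
  structure(list(slope = slope, intercept = intercept,
                 projected_first_decile = max(0, proj), clamped = clamped),
            class = "decile_projection")
}

#' @export
print.decile_projection <- function(x, ...) {
  cat("decile_projection: slope", round(x$slope, 3), "-> first decile",
      round(x$projected_first_decile, 1),
      if (x$clamped) "(clamped at 0)" else "", "\n")
  invisible(x)
}

#' Estimate DE genes escaping detection in the first decile
#'
#' Difference between the projected and observed first-decile counts,
#' clamped at zero, with the implied fraction of the tested gene universe.
#'
#' @param projection a `decile_projection`.
#' @param observed_first_decile observed count in the `[0,10)` bin.
#' @param universe_n optional number of tested genes, used only for the
#'   reported fraction.
#' @return list: `estimated_missed`, `projected`, `observed`,
#'   `fraction_of_universe` (NA when `universe_n` missing).
#' @export
estimate_missed <- function(projection, observed_first_decile,
                            universe_n = NULL) {
  stopifnot(inherits(projection, "decile_projection"))
  check_number(observed_first_decile, "observed_first_decile", lower = 0)
  missed <- max(0, projection$projected_first_decile - observed_first_decile)
  list(estimated_missed = missed,
       projected = projection$projected_first_decile,
       observed = observed_first_decile,
       fraction_of_universe = if (is.null(universe_n)) NA_real_ else
         missed / universe_n)
}
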