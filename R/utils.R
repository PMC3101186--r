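## One quantile convention is used everywhere (winsorization, empirical
## confidence limits, null thresholds): linear interpolation between order
## statistics, stats::quantile type 7.
QUANTILE_TYPE <- 7L

#' Empirical quantile under the package-wide convention
#'
#' All quantile-based computations (winsorized means, empirical upper
#' confidence limits, simulation null thresholds) share this single rule:
#' linear interpolation between order statistics (type 7).
#'
#' @param x numeric vector.
#' @param probs probabilities in \[0, 1\].
#' @return Quantiles, unnamed.
#' @export
qi_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = QUANTILE_TYPE, names = FALSE, na.rm = FALSE)
}

#' Winsorized mean
#'
#' Mean after replacing every value strictly above the `rho` quantile with
#' that quantile, the robust array-level summary used for quality indices:
#' `rho = 0.95` caps the top 5% of standardized distances.
#'
#' @param x numeric vector without `NA`.
#' @param rho winsorization quantile in (0, 1).
#' @return The winsorized mean (scalar).
#' @export
winsorized_mean <- function(x, rho = 0.95) {
  stopifnot(rho > 0, rho < 1)
  cap <- qi_quantile(x, rho)
  mean(pmin(x, cap))
}

## rho-trimmed mean: drop values above the rho quantile, then average
trimmed_mean_upper <- function(x, rho) {
  cap <- qi_quantile(x, rho)
  mean(x[x <= cap])
}

SUMMARY_KINDS <- c("winsorized_mean", "median", "trimmed_mean")

summarize_qi <- function(x, summary_kind, rho) {
  switch(summary_kind,
         winsorized_mean = winsorized_mean(x, rho),
         median = stats::median(x),
         trimmed_mean = trimmed_mean_upper(x, rho),
         stop("unknown summary_kind: ", summary_kind))
}

## per-column QI summary of a q matrix (SNPs x arrays); NA cells dropped
## per column; columns with fewer than min_snps usable values give NA
column_qi <- function(qmat, summary_kind, rho, min_snps = 1L) {
  apply(qmat, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < min_snps) return(NA_real_)
    summarize_qi(col, summary_kind, rho)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
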