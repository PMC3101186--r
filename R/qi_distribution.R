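#' Fit a lognormal distribution to array-level quality indices
#'
#' Array-level quality indices of good-quality reference arrays are well
#' described by lognormal distributions, so the fit works on the log scale:
#' `meanlog`/`sdlog` are the sample mean and SD (n - 1 denominator) of the
#' log values. Goodness of fit is assessed with a one-sample
#' Kolmogorov-Smirnov test against the fitted normal (see
#' [ks_lognormal()]).
#'
#' @param qi_values positive numeric vector, length >= 10.
#' @return A `lognormal_fit` list with `meanlog`, `sdlog`, `n`,
#'   `ks_statistic`, `ks_pvalue`.
#' @export
fit_lognormal <- function(qi_values) {
  qi_values <- as.numeric(qi_values)
  if (length(qi_values) < 10L) stop("need at least 10 values to fit")
  if (any(is.na(qi_values)) || any(qi_values <= 0)) {
    stop("all quality-index values must be positive and non-missing")
  }
  lx <- log(qi_values)
  sdlog <- stats::sd(lx)
  if (sdlog == 0) stop("degenerate fit: zero variance on the log scale")
  fit <- structure(list(meanlog = mean(lx), sdlog = sdlog,
                        n = length(qi_values)),
                   class = "lognormal_fit")
  ks <- ks_lognormal(qi_values, fit)
  fit$ks_statistic <- ks$statistic
  fit$ks_pvalue <- ks$pvalue
  fit
}

#' Kolmogorov-Smirnov test of lognormality
#'
#' One-sample KS test of the log values against Normal(meanlog, sdlog)
#' with the fitted parameters plugged in as if known, and the standard
#' asymptotic KS p-value. With estimated parameters this plain test is
#' conservative (the true rejection rate at alpha sits below alpha); no
#' Lilliefors-type correction is applied.
#'
#' @param qi_values positive numeric vector, length >= 10.
#' @param fit `lognormal_fit` (or any list with `meanlog`, `sdlog`).
#' @return List with `statistic` and `pvalue`.
#' @export
ks_lognormal <- function(qi_values, fit) {
  if (length(qi_values) < 10L) stop("need at least 10 values")
  if (any(is.na(qi_values)) || any(qi_values <= 0)) {
    stop("all quality-index values must be positive and non-missing")
  }
  kt <- suppressWarnings(
    stats::ks.test(log(qi_values), "pnorm", mean = fit$meanlog,
                   sd = fit$sdlog, exact = FALSE)
  )
  list(statistic = unname(kt$statistic), pvalue = unname(kt$p.value))
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("lognormal fit: meanlog = %.4f, sdlog = %.4f (n = %d), KS D = %.4f, p = %.3f\n",
              x$meanlog, x$sdlog, x$n, x$ks_statistic, x$ks_pvalue))
  invisible(x)
}

#' Build a quality-index reference (upper confidence limits)
#'
#' For each stratum of an array-level QI table — combination of array
#' label, scope, index kind, summary statistic and rho — the reference
#' stores upper confidence limits at the requested levels. The default
#' `empirical` source takes level-quantiles of the observed reference QIs
#' (the package-wide interpolation rule); the `lognormal` source uses the
#' fitted quantiles `exp(meanlog + z_level * sdlog)`. The stratum's QI mean
#' and SD are recorded for heatmap level coloring. Empirical strata with
#' fewer than `min_arrays` reference arrays are skipped with a warning.
#'
#' @param qi_table `array_qi_table` of reference (good-quality) arrays.
#' @param levels confidence levels (default 0.95, 0.975, 0.99).
#' @param source `"empirical"` (default) or `"lognormal"`.
#' @param population_label label of the reference population.
#' @param min_arrays minimum reference arrays per stratum (default 20).
#' @return A `qi_reference` data frame, one row per (stratum, level).
#' @export
build_qi_reference <- function(qi_table, levels = c(0.95, 0.975, 0.99),
                               source = c("empirical", "lognormal"),
                               population_label = "study", min_arrays = 20L) {
  stopifnot(inherits(qi_table, "array_qi_table"),
            all(levels > 0), all(levels < 1))
  source <- match.arg(source)
  levels <- sort(levels)
  strata <- unique(qi_table[, c("array_label", "scope", "index_kind",
                                "summary_kind", "rho")])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    sel <- qi_table$array_label == st$array_label &
      qi_table$scope == st$scope & qi_table$index_kind == st$index_kind &
      qi_table$summary_kind == st$summary_kind & qi_table$rho == st$rho
    vals <- qi_table$qi_value[sel]
    if (source == "empirical" && length(vals) < min_arrays) {
      warning(sprintf("stratum %s/%s skipped: only %d reference arrays (< %d)",
                      st$array_label, st$scope, length(vals), min_arrays))
      next
    }
    limits <- if (source == "empirical") {
      qi_quantile(vals, levels)
    } else {
      f <- fit_lognormal(vals)
      exp(f$meanlog + stats::qnorm(levels) * f$sdlog)
    }
    out[[length(out) + 1L]] <- data.frame(
      population_label = population_label, array_label = st$array_label,
      scope = st$scope, index_kind = st$index_kind,
      summary_kind = st$summary_kind, rho = st$rho,
      level = levels, limit = limits, source = source,
      mu_qi = mean(vals), sigma_qi = stats::sd(vals),
      n_arrays = length(vals), row.names = NULL)
  }
  if (length(out) == 0L) stop("no stratum had enough reference arrays")
  structure(do.call(rbind, out), class = c("qi_reference", "data.frame"))
}

#' Construct a quality-index reference from known limits
#'
#' Builds a `qi_reference` directly from externally supplied upper
#' confidence limits (e.g. a published reference database) instead of from
#' reference arrays.
#'
#' @param limits data frame with columns `array_label`, `level`, `limit`
#'   and optionally `scope`, `index_kind`, `summary_kind`, `rho`,
#'   `mu_qi`, `sigma_qi`, `n_arrays`.
#' @param population_label reference population label.
#' @return A `qi_reference`.
#' @export
qi_reference_from_limits <- function(limits, population_label = "external") {
  limits <- as.data.frame(limits)
  stopifnot(all(c("array_label", "level", "limit") %in% names(limits)))
  defaults <- list(scope = "GENOME", index_kind = "nearest_mean",
                   summary_kind = "winsorized_mean", rho = 0.95,
                   mu_qi = NA_real_, sigma_qi = NA_real_,
                   n_arrays = NA_integer_, source = "empirical")
  for (nm in names(defaults)) {
    if (is.null(limits[[nm]])) limits[[nm]] <- defaults[[nm]]
  }
  limits$population_label <- population_label
  cols <- c("population_label", "array_label", "scope", "index_kind",
            "summary_kind", "rho", "level", "limit", "source", "mu_qi",
            "sigma_qi", "n_arrays")
  structure(limits[, cols], class = c("qi_reference", "data.frame"))
}

#' Flag poor-quality arrays against a quality-index reference
#'
#' An array is flagged as questionable when its quality index strictly
#' exceeds the reference's upper confidence limit at the chosen level; an
#' index exactly equal to the limit is not flagged. Flags are reported per
#' (sample, array label), so a merged-array index is judged against the
#' Merge stratum separately from its component arrays.
#'
#' @param qi_table `array_qi_table` of the arrays under evaluation
#'   (GENOME-scope rows are used).
#' @param ref `qi_reference`.
#' @param level confidence level; must be present in `ref` (default 0.95).
#' @return A `detection_report` data frame with columns `sample_id`,
#'   `array_label`, `qi_value`, `limit`, `level`, `flag`.
#' @export
detect_poor_arrays <- function(qi_table, ref, level = 0.95) {
  stopifnot(inherits(qi_table, "array_qi_table"), inherits(ref, "qi_reference"))
  qt <- qi_table[qi_table$scope == "GENOME", , drop = FALSE]
  if (nrow(qt) == 0L) stop("qi_table has no GENOME-scope rows")
  out <- qt[, c("sample_id", "array_label", "qi_value")]
  out$limit <- NA_real_
  for (i in seq_len(nrow(qt))) {
    sel <- ref$array_label == qt$array_label[i] & ref$scope == "GENOME" &
      ref$index_kind == qt$index_kind[i] &
      ref$summary_kind == qt$summary_kind[i] &
      ref$rho == qt$rho[i] & abs(ref$level - level) < 1e-9
    if (!any(sel)) {
      stop(sprintf(
        "no reference stratum for array '%s' (scope GENOME, index %s, summary %s, rho %g, level %g)",
        qt$array_label[i], qt$index_kind[i], qt$summary_kind[i], qt$rho[i], level))
    }
    out$limit[i] <- ref$limit[which(sel)[1L]]
  }
  out$level <- level
  out$flag <- out$qi_value > out$limit
  rownames(out) <- NULL
  structure(out, class = c("detection_report", "data.frame"))
}

#' Compare quality-index distributions of two groups
#'
#' Compares two groups of array-level quality indices (e.g. ethnic groups
#' or laboratories) on the log scale: a two-sample Z test for equality of
#' means (unpooled variances, normal reference), an F test for equality of
#' variances, and a two-sample Kolmogorov-Smirnov test for equality of the
#' full sampling distributions. All tests are two-sided.
#'
#' @param qi_a,qi_b positive numeric vectors, each length >= 10.
#' @param labels character pair naming the groups.
#' @return A `group_comparison` list with `p_mean`, `p_var`, `p_ks`,
#'   `group_labels`.
#' @export
compare_groups <- function(qi_a, qi_b, labels = c("A", "B")) {
  for (v in list(qi_a, qi_b)) {
    if (length(v) < 10L) stop("each group needs at least 10 values")
    if (any(is.na(v)) || any(v <= 0)) stop("all values must be positive and non-missing")
  }
  la <- log(qi_a); lb <- log(qi_b)
  se <- sqrt(stats::var(la) / length(la) + stats::var(lb) / length(lb))
  z <- (mean(la) - mean(lb)) / se
  p_mean <- 2 * stats::pnorm(-abs(z))
  p_var <- stats::var.test(la, lb)$p.value
  p_ks <- suppressWarnings(stats::ks.test(la, lb, exact = FALSE))$p.value
  structure(list(p_mean = p_mean, p_var = p_var, p_ks = p_ks,
                 group_labels = labels),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("QI comparison %s vs %s: P_mean = %.3g, P_var = %.3g, P_KS = %.3g\n",
              x$group_labels[1], x$group_labels[2], x$p_mean, x$p_var, x$p_ks))
  invisible(x)
}
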