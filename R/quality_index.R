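new_snp_qi_matrix <- function(q, annotation, sample_ids, index_kind) {
  structure(list(q = q, annotation = annotation, sample_ids = sample_ids,
                 index_kind = index_kind),
            class = "snp_qi_matrix")
}

#' Genotype-based SNP-level quality index (q1)
#'
#' The standardized distance of an individual-level allele frequency from
#' its called genotype's reference band: `q = |lambda - mu_G| / sigma_G`
#' for cells with a called genotype `G` and an eligible reference cell.
#' No-calls, missing AFs and ineligible reference cells give missing q.
#'
#' @param af [af_matrix()] aligned with `genotypes`.
#' @param genotypes [genotype_matrix()].
#' @param ref `af_reference` covering the SNPs.
#' @return A `snp_qi_matrix` (`index_kind = "genotype_based"`).
#' @export
snp_qi_genotype <- function(af, genotypes, ref) {
  stopifnot(inherits(af, "af_matrix"), inherits(genotypes, "genotype_matrix"),
            inherits(ref, "af_reference"))
  check_alignment(af, genotypes, "AF", "genotype")
  snp_ids <- af$annotation$snp_id
  if (!any(snp_ids %in% ref$snp_id)) stop("no overlapping SNPs between AF matrix and reference")
  wide <- reference_wide(ref, snp_ids)
  q <- matrix(NA_real_, nrow(af$af), ncol(af$af))
  for (g in c("AA", "AB", "BB")) {
    sel <- genotypes$calls == g & !is.na(af$af)
    qg <- abs(af$af - wide[[g]]$mean) / wide[[g]]$sd  # per-SNP vectors recycle down columns
    q[sel] <- qg[sel]
  }
  new_snp_qi_matrix(q, af$annotation, af$sample_ids, "genotype_based")
}

#' Nearest-mean-based SNP-level quality index (q2)
#'
#' Standardized distance to the genotype class whose reference mean is
#' closest to the observed allele frequency; needs no genotype calls, so it
#' stays informative when calling is itself compromised (e.g. copy-number
#' aberrations). For each non-missing AF, `G*` minimizes `|lambda - mu_G|`
#' over eligible reference cells and `q = |lambda - mu_G*| / sigma_G*`.
#' When two classes are exactly equidistant the one yielding the smaller q
#' (larger sigma) is used: a deterministic, conservative tie-break.
#'
#' @param af [af_matrix()].
#' @param ref `af_reference` covering the SNPs.
#' @return A `snp_qi_matrix` (`index_kind = "nearest_mean"`).
#' @export
snp_qi_nearest <- function(af, ref) {
  stopifnot(inherits(af, "af_matrix"), inherits(ref, "af_reference"))
  snp_ids <- af$annotation$snp_id
  if (!any(snp_ids %in% ref$snp_id)) stop("no overlapping SNPs between AF matrix and reference")
  wide <- reference_wide(ref, snp_ids)
  q <- nearest_mean_q(af$af,
                      mu = lapply(wide, `[[`, "mean"),
                      sdv = lapply(wide, `[[`, "sd"))
  new_snp_qi_matrix(q, af$annotation, af$sample_ids, "nearest_mean")
}

## lam: SNPs x samples matrix; mu/sdv: lists of per-SNP vectors (AA, AB, BB),
## NA where ineligible. Vectorized nearest-mean distance with the
## smaller-q tie-break.
nearest_mean_q <- function(lam, mu, sdv) {
  d <- lapply(mu, function(m) abs(lam - m))
  big <- function(x) { x[is.na(x)] <- Inf; x }
  dmin <- pmin(big(d[[1]]), big(d[[2]]), big(d[[3]]))
  q <- NULL
  for (k in 1:3) {
    qk <- d[[k]] / sdv[[k]]
    qk[is.na(qk) | big(d[[k]]) > dmin] <- Inf
    q <- if (is.null(q)) qk else pmin(q, qk)
  }
  q[!is.finite(q) | is.na(lam)] <- NA_real_
  q
}

#' Array-level quality index
#'
#' Summarizes the SNP-level standardized distances of each array into one
#' number per scope (each chromosome, plus the genome-wide scope `GENOME`).
#' The default summary is the winsorized mean: distances strictly above the
#' `rho` quantile are replaced by that quantile before averaging, tolerating
#' the handful of extreme SNPs that occur even on good arrays. `median` and
#' `trimmed_mean` (drop values above the `rho` quantile) are robust
#' alternatives. Scopes with fewer than `min_snps` usable values are
#' skipped with a warning.
#'
#' @param snp_qi `snp_qi_matrix` from [snp_qi_genotype()] or
#'   [snp_qi_nearest()].
#' @param rho winsorization quantile (default 0.95).
#' @param summary_kind one of `"winsorized_mean"`, `"median"`,
#'   `"trimmed_mean"`.
#' @param scopes `"both"` (default), `"genome"` or `"chromosome"`.
#' @param min_snps minimum usable SNPs per scope (default 30).
#' @param array_label label for the report; defaults to the annotation's
#'   label when unique.
#' @return An `array_qi_table` data frame with columns `sample_id`,
#'   `array_label`, `scope`, `index_kind`, `summary_kind`, `rho`,
#'   `qi_value`, `n_snps_used`.
#' @export
array_qi <- function(snp_qi, rho = 0.95, summary_kind = "winsorized_mean",
                     scopes = c("both", "genome", "chromosome"),
                     min_snps = 30L, array_label = NULL) {
  stopifnot(inherits(snp_qi, "snp_qi_matrix"), rho > 0, rho < 1)
  summary_kind <- match.arg(summary_kind, SUMMARY_KINDS)
  scopes <- match.arg(scopes)
  if (is.null(array_label)) {
    labs <- unique(snp_qi$annotation$array_label)
    array_label <- if (length(labs) == 1L) labs else paste(labs, collapse = "+")
  }
  scope_rows <- function(qmat, scope) {
    n_used <- colSums(!is.na(qmat))
    keep <- n_used >= min_snps
    if (!all(keep)) {
      warning(sprintf("scope %s skipped for %d array(s): fewer than %d usable SNPs",
                      scope, sum(!keep), min_snps))
    }
    if (!any(keep)) return(NULL)
    vals <- column_qi(qmat[, keep, drop = FALSE], summary_kind, rho)
    data.frame(sample_id = snp_qi$sample_ids[keep], array_label = array_label,
               scope = scope, index_kind = snp_qi$index_kind,
               summary_kind = summary_kind, rho = rho, qi_value = vals,
               n_snps_used = as.integer(n_used[keep]), row.names = NULL)
  }
  out <- list()
  if (scopes %in% c("both", "genome")) {
    out <- c(out, list(scope_rows(snp_qi$q, "GENOME")))
  }
  if (scopes %in% c("both", "chromosome")) {
    for (chr in unique(snp_qi$annotation$chromosome)) {
      sel <- snp_qi$annotation$chromosome == chr
      out <- c(out, list(scope_rows(snp_qi$q[sel, , drop = FALSE], chr)))
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no scope had at least ", min_snps, " usable SNPs")
  structure(out, class = c("array_qi_table", "data.frame"))
}

#' Merged-array quality index
#'
#' Quality index of the pooled SNP set of companion arrays (e.g. the
#' "Merge" of the Nsp and Sty chips): the SNP-level distances of all parts
#' are pooled per sample and then summarized exactly as [array_qi()] —
#' pooling of distances, never averaging of part-level indices.
#'
#' @param snp_qi_parts list of `snp_qi_matrix` objects sharing samples,
#'   with disjoint SNP sets and a common `index_kind`.
#' @param array_label label for the pooled report (default "Merge").
#' @inheritParams array_qi
#' @return An `array_qi_table`.
#' @export
merge_array_qi <- function(snp_qi_parts, rho = 0.95,
                           summary_kind = "winsorized_mean",
                           scopes = "both", min_snps = 30L,
                           array_label = "Merge") {
  stopifnot(is.list(snp_qi_parts), length(snp_qi_parts) >= 2L)
  first <- snp_qi_parts[[1L]]
  all_ids <- first$annotation$snp_id
  for (p in snp_qi_parts[-1L]) {
    if (!identical(p$sample_ids, first$sample_ids)) {
      stop("all parts must share the same sample_ids")
    }
    if (p$index_kind != first$index_kind) stop("parts mix index kinds")
    overlap <- intersect(p$annotation$snp_id, all_ids)
    if (length(overlap) > 0L) {
      stop("overlapping snp_id across parts: ", overlap[1L])
    }
    all_ids <- c(all_ids, p$annotation$snp_id)
  }
  pooled <- new_snp_qi_matrix(
    q = do.call(rbind, lapply(snp_qi_parts, `[[`, "q")),
    annotation = do.call(rbind, lapply(snp_qi_parts, `[[`, "annotation")),
    sample_ids = first$sample_ids,
    index_kind = first$index_kind
  )
  array_qi(pooled, rho = rho, summary_kind = summary_kind, scopes = scopes,
           min_snps = min_snps, array_label = array_label)
}

#' Genotype call rate
#'
#' Per-sample fraction of SNPs with a non-missing genotype call, computed
#' genome-wide and per chromosome.
#'
#' @param genotypes [genotype_matrix()].
#' @return A `gcr_table` data frame with columns `sample_id`, `scope`,
#'   `gcr`, `n_called`, `n_total`.
#' @export
compute_gcr <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (nrow(genotypes$annotation) == 0L) stop("empty genotype matrix")
  rows <- function(calls, scope) {
    called <- colSums(calls != "NC")
    data.frame(sample_id = genotypes$sample_ids, scope = scope,
               gcr = called / nrow(calls), n_called = as.integer(called),
               n_total = nrow(calls), row.names = NULL)
  }
  out <- list(rows(genotypes$calls, "GENOME"))
  for (chr in unique(genotypes$annotation$chromosome)) {
    sel <- genotypes$annotation$chromosome == chr
    out <- c(out, list(rows(genotypes$calls[sel, , drop = FALSE], chr)))
  }
  structure(do.call(rbind, out), class = c("gcr_table", "data.frame"))
}
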