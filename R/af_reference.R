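new_af_reference <- function(tab, min_count, sd_floor, population_label) {
  tab$snp_id <- as.character(tab$snp_id)
  tab$genotype <- as.character(tab$genotype)
  tab$n <- as.integer(tab$n)
  tab$eligible <- !is.na(tab$mean) & !is.na(tab$sd) &
    tab$n >= min_count & tab$sd > sd_floor
  rownames(tab) <- NULL
  structure(tab, class = c("af_reference", "data.frame"),
            min_count = as.integer(min_count), sd_floor = sd_floor,
            population_label = population_label)
}

#' Build a genotype-specific AF reference
#'
#' For every SNP and called genotype class (AA/AB/BB) the reference stores
#' the mean and sample standard deviation (n - 1 denominator) of the
#' individual-level allele frequencies of the samples carrying that call.
#' These per-class locations and spreads are what the standardized-distance
#' quality indices measure departures from. A (SNP, genotype) cell is only
#' eligible for index computation when it rests on at least `min_count`
#' samples and its SD exceeds `sd_floor`; ineligible cells are excluded
#' rather than floored, since flooring SDs would silently deflate distances.
#'
#' @param af [af_matrix()] aligned with `genotypes`.
#' @param genotypes [genotype_matrix()].
#' @param min_count minimum samples per cell (default 3, must be >= 2).
#' @param sd_floor smallest usable SD (default 1e-4).
#' @param population_label free-text label of the reference population.
#' @return An `af_reference` data frame (one row per SNP x genotype class)
#'   with columns `snp_id`, `genotype`, `mean`, `sd`, `n`, the annotation
#'   columns, and the derived `eligible` flag.
#' @export
build_af_reference <- function(af, genotypes, min_count = 3L, sd_floor = 1e-4,
                               population_label = "study") {
  stopifnot(inherits(af, "af_matrix"), inherits(genotypes, "genotype_matrix"),
            min_count >= 2L)
  check_alignment(af, genotypes, "AF", "genotype")
  if (length(af$sample_ids) == 0L) stop("zero aligned samples")
  ann <- af$annotation
  classes <- c("AA", "AB", "BB")
  rows <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    g <- classes[k]
    lam <- af$af
    lam[genotypes$calls != g] <- NA_real_
    n <- rowSums(!is.na(lam))
    mu <- rowMeans(lam, na.rm = TRUE)
    ## sample SD with n-1 denominator, rowwise
    ss <- rowSums(sweep(lam, 1L, mu, "-")^2, na.rm = TRUE)
    sdv <- ifelse(n >= 2L, sqrt(ss / pmax(n - 1L, 1L)), NA_real_)
    mu[n == 0L] <- NA_real_
    rows[[k]] <- data.frame(snp_id = ann$snp_id, genotype = g, mean = mu,
                            sd = sdv, n = as.integer(n),
                            chromosome = ann$chromosome,
                            position_bp = ann$position_bp,
                            array_label = ann$array_label,
                            row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(match(tab$snp_id, ann$snp_id), tab$genotype), ]
  new_af_reference(tab, min_count, sd_floor, population_label)
}

#' Construct an AF reference from explicit per-cell parameters
#'
#' Assembles an `af_reference` directly from known genotype-class means and
#' SDs, e.g. the generating parameters of a simulation or an externally
#' supplied reference database.
#'
#' @param tab data frame with columns `snp_id`, `genotype`, `mean`, `sd`,
#'   `n`, `chromosome`, `position_bp`, `array_label`.
#' @param min_count,sd_floor eligibility rules (see [build_af_reference()]).
#' @param population_label reference population label.
#' @return An `af_reference`.
#' @export
af_reference_from_params <- function(tab, min_count = 3L, sd_floor = 1e-4,
                                     population_label = "synthetic") {
  new_af_reference(as.data.frame(tab), min_count, sd_floor, population_label)
}

#' Subset an AF reference
#'
#' Restrict a reference to one chromosome or an explicit SNP-id set, e.g.
#' for per-chromosome quality indices. Eligibility flags are preserved.
#'
#' @param ref `af_reference`.
#' @param chromosome single chromosome label, or `NULL`.
#' @param snp_ids character vector of SNP ids, or `NULL`. Exactly one of
#'   `chromosome`/`snp_ids` must be given.
#' @return The restricted `af_reference`.
#' @export
subset_reference <- function(ref, chromosome = NULL, snp_ids = NULL) {
  stopifnot(inherits(ref, "af_reference"))
  if (is.null(chromosome) == is.null(snp_ids)) {
    stop("give exactly one of 'chromosome' or 'snp_ids'")
  }
  keep <- if (!is.null(chromosome)) ref$chromosome %in% chromosome
          else ref$snp_id %in% snp_ids
  if (!any(keep)) stop("subset selects no SNPs")
  out <- ref[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(ref), min_count = attr(ref, "min_count"),
            sd_floor = attr(ref, "sd_floor"),
            population_label = attr(ref, "population_label"))
}

## internal: wide per-genotype views of a reference aligned to snp_ids;
## ineligible cells become NA
reference_wide <- function(ref, snp_ids) {
  out <- list()
  for (g in c("AA", "AB", "BB")) {
    sub <- ref[ref$genotype == g, , drop = FALSE]
    idx <- match(snp_ids, sub$snp_id)
    mu <- sub$mean[idx]; sdv <- sub$sd[idx]
    ok <- !is.na(idx) & sub$eligible[pmax(idx, 1L)]
    mu[!ok] <- NA_real_; sdv[!ok] <- NA_real_
    out[[g]] <- list(mean = mu, sd = sdv)
  }
  out
}
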