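#' Estimate the coefficient of preferential amplification/hybridization
#'
#' The two alleles of a SNP are not amplified and hybridized with equal
#' efficiency, so the raw intensity ratio is biased away from 1 in
#' heterozygotes. The CPA kappa of a SNP is estimated as the arithmetic
#' mean of the A/B intensity ratio over samples called heterozygous (AB)
#' with a positive B signal. SNPs with fewer than `min_het` usable
#' heterozygotes fall back to kappa = 1 (no adjustment) and are flagged.
#'
#' @param intensities [intensity_matrix()] aligned with `genotypes`.
#' @param genotypes [genotype_matrix()] providing the AB calls.
#' @param min_het minimum number of usable heterozygotes (default 3);
#'   the ratio mean is unstable on fewer points.
#' @return A `cpa_table` data frame with columns `snp_id`, `kappa`,
#'   `n_het`, `fallback`.
#' @export
estimate_cpa <- function(intensities, genotypes, min_het = 3L) {
  stopifnot(inherits(intensities, "intensity_matrix"),
            inherits(genotypes, "genotype_matrix"), min_het >= 1L)
  check_alignment(intensities, genotypes, "intensity", "genotype")
  use <- genotypes$calls == "AB" & !is.na(intensities$intensity_b) &
    intensities$intensity_b > 0 & !is.na(intensities$intensity_a)
  ratio <- intensities$intensity_a / intensities$intensity_b
  ratio[!use] <- NA_real_
  n_het <- rowSums(use)
  kappa <- rowMeans(ratio, na.rm = TRUE)
  fallback <- n_het < min_het
  kappa[fallback] <- 1
  structure(
    data.frame(snp_id = intensities$annotation$snp_id, kappa = kappa,
               n_het = as.integer(n_het), fallback = fallback,
               row.names = NULL),
    class = c("cpa_table", "data.frame")
  )
}

#' Estimate individual-level allele frequencies from intensities
#'
#' The individual-level allele frequency of allele A is the CPA-adjusted
#' intensity share `lambda = I_A / (I_A + kappa * I_B)`, clipped to
#' \[0, 1\]. Dividing the B signal's weight by nothing but kappa makes a
#' perfectly behaved heterozygote (`I_A = kappa * I_B`) land exactly at
#' 0.5, which is what the three-band AF profile requires. Cells where
#' `I_A + kappa * I_B = 0` (or either intensity is missing) are missing.
#'
#' @param intensities [intensity_matrix()].
#' @param cpa `cpa_table` covering every SNP (see [estimate_cpa()]).
#' @return An [af_matrix()].
#' @export
estimate_af <- function(intensities, cpa) {
  stopifnot(inherits(intensities, "intensity_matrix"),
            inherits(cpa, "cpa_table"))
  idx <- match(intensities$annotation$snp_id, cpa$snp_id)
  if (anyNA(idx)) {
    stop("SNP missing from CPA table: ",
         intensities$annotation$snp_id[which(is.na(idx))[1L]])
  }
  kappa <- cpa$kappa[idx]
  denom <- intensities$intensity_a + kappa * intensities$intensity_b
  lambda <- intensities$intensity_a / denom
  lambda[!is.na(denom) & denom == 0] <- NA_real_
  lambda <- pmin(pmax(lambda, 0), 1)
  af_matrix(lambda, intensities$annotation, intensities$sample_ids)
}

#' Genotype-implied allele frequency
#'
#' The allele-A frequency a called genotype implies within one individual:
#' `AA` carries two A alleles (1.0), `AB` one (0.5), `BB` none (0.0).
#' No-calls map to `NA`. Used by the genotype-based AF plot.
#'
#' @param genotype character vector of genotype codes.
#' @return Numeric vector in \{0, 0.5, 1\} with `NA` for `NC`.
#' @export
genotype_implied_af <- function(genotype) {
  mapped <- GENOTYPE_SYNONYMS[as.character(genotype)]
  if (anyNA(mapped)) {
    stop("unknown genotype code: ", as.character(genotype)[which(is.na(mapped))[1L]])
  }
  unname(c(AA = 1, AB = 0.5, BB = 0, NC = NA_real_)[mapped])
}
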