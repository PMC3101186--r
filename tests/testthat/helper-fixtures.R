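## Toy fixtures built in code, plus independent brute-force oracles for the
## quantile/winsorization/KS computations. The oracles deliberately share no
## code with the package internals.

toy_annotation <- function(n = 2L, chromosome = rep("1", n), array_label = "Nsp") {
  data.frame(snp_id = paste0("rs", seq_len(n)), chromosome = chromosome,
             position_bp = seq_len(n) * 100L, array_label = array_label)
}

toy_genotypes <- function(calls, chromosome = NULL, array_label = "Nsp") {
  calls <- as.matrix(calls)
  ann <- toy_annotation(nrow(calls),
                        chromosome = chromosome %||% rep("1", nrow(calls)),
                        array_label = array_label)
  if (is.null(colnames(calls))) colnames(calls) <- paste0("S", seq_len(ncol(calls)))
  genotype_matrix(calls, ann)
}

toy_af <- function(af, chromosome = NULL, array_label = "Nsp") {
  af <- as.matrix(af)
  ann <- toy_annotation(nrow(af), chromosome = chromosome %||% rep("1", nrow(af)),
                        array_label = array_label)
  if (is.null(colnames(af))) colnames(af) <- paste0("S", seq_len(ncol(af)))
  af_matrix(af, ann)
}

## reference with one row per SNP x genotype from explicit vectors
toy_reference <- function(n_snps, mu = c(AA = 0.95, AB = 0.5, BB = 0.05),
                          sdv = c(AA = 0.05, AB = 0.1, BB = 0.05), n = 50L) {
  ann <- toy_annotation(n_snps)
  tab <- do.call(rbind, lapply(c("AA", "AB", "BB"), function(g) {
    data.frame(snp_id = ann$snp_id, genotype = g, mean = mu[[g]], sd = sdv[[g]],
               n = n, chromosome = ann$chromosome,
               position_bp = ann$position_bp, array_label = ann$array_label)
  }))
  af_reference_from_params(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## type-7 quantile by the textbook order-statistic interpolation formula
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

## winsorized mean: sort, cap everything above the rho quantile, average
oracle_winsorized_mean <- function(x, rho) {
  cap <- oracle_quantile(x, rho)
  y <- x
  y[y > cap] <- cap
  sum(y) / length(y)
}

## one-sample KS statistic: max CDF discrepancy over the sorted sample
oracle_ks_stat <- function(x, cdf) {
  xs <- sort(x)
  n <- length(xs)
  fm <- cdf(xs)
  max(seq_len(n) / n - fm, fm - (seq_len(n) - 1) / n)
}
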