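#' Beta parameters by moment matching
#'
#' Given a target mean `mu` in (0, 1) and variance below `mu * (1 - mu)`,
#' returns the Beta(alpha, beta) shape parameters with exactly that mean
#' and variance: `c = mu (1 - mu) / v - 1`, `alpha = mu c`,
#' `beta = (1 - mu) c`. Variances at or above the beta-family bound
#' `mu (1 - mu)` are clamped to 0.99 of the bound with a warning, since
#' the beta family cannot represent them.
#'
#' @param mu mean(s) in (0, 1); vectorized.
#' @param variance target variance(s), > 0.
#' @return List with numeric `alpha` and `beta`.
#' @export
beta_moment_params <- function(mu, variance) {
  stopifnot(all(mu > 0), all(mu < 1), all(variance > 0))
  vmax <- mu * (1 - mu)
  over <- variance >= vmax
  if (any(over)) {
    warning(sprintf("%d variance value(s) at or above the beta bound mu*(1-mu); clamped to 0.99 of the bound",
                    sum(over)))
    variance <- ifelse(over, 0.99 * vmax, variance)
  }
  cc <- vmax / variance - 1
  list(alpha = mu * cc, beta = (1 - mu) * cc)
}

## quiet vectorized clamp used by the simulation kernel; returns shapes and
## the count of clamped cells
beta_shapes_clamped <- function(mu, variance) {
  vmax <- mu * (1 - mu)
  over <- variance >= vmax
  variance <- ifelse(over, 0.99 * vmax, variance)
  cc <- vmax / variance - 1
  list(alpha = mu * cc, beta = (1 - mu) * cc, n_clamped = sum(over))
}

#' Synthesize per-SNP generative parameters
#'
#' Stands in for the population-level genotype frequencies and AF band
#' parameters that a real reference data set would provide. Each SNP gets
#' a minor-allele frequency drawn uniformly from `maf_range`, genotype
#' probabilities by Hardy-Weinberg equilibrium (p^2, 2pq, q^2), and
#' genotype-class AF bands centered at the `band_mu` defaults (AA 0.93,
#' AB 0.50, BB 0.07 — the pure-allele bands pulled slightly inward, as
#' background hybridization does on real chips) with systematic variance
#' `band_v` (0.0015, i.e. a within-band SD of about 0.039). Small per-SNP
#' jitter (normal on the means, lognormal on the variances) keeps SNPs
#' from being identical.
#'
#' @param n_snps number of SNPs.
#' @param maf_range minor-allele frequency range within (0, 0.5\].
#' @param band_mu named numeric (AA, AB, BB) band means.
#' @param band_v systematic variance of every band.
#' @param mu_jitter_sd SD of the normal jitter on band means (default 0.005).
#' @param v_jitter_sdlog SD of the log-scale jitter on band variances
#'   (default 0.1).
#' @param chromosome,array_label annotation for the synthetic SNPs.
#' @param seed optional integer seed.
#' @return A `snp_generative_params` data frame with genotype
#'   probabilities (`p_aa`, `p_ab`, `p_bb`), band means (`mu_aa`, `mu_ab`,
#'   `mu_bb`) and systematic variances (`v_aa`, `v_ab`, `v_bb`).
#' @export
synth_population <- function(n_snps, maf_range = c(0.05, 0.5),
                             band_mu = c(AA = 0.93, AB = 0.50, BB = 0.07),
                             band_v = 0.0015, mu_jitter_sd = 0.005,
                             v_jitter_sdlog = 0.1, chromosome = "19",
                             array_label = "SIM", seed = NULL) {
  stopifnot(n_snps >= 1L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], band_v > 0)
  if (!is.null(seed)) set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  p <- 1 - maf  # frequency of allele A; minor allele is B
  jitter_mu <- function(center) {
    pmin(pmax(center + stats::rnorm(n_snps, 0, mu_jitter_sd), 0.01), 0.99)
  }
  jitter_v <- function() band_v * exp(stats::rnorm(n_snps, 0, v_jitter_sdlog))
  out <- data.frame(
    snp_id = sprintf("SIM%06d", seq_len(n_snps)),
    chromosome = chromosome,
    position_bp = seq_len(n_snps) * 1000L,
    array_label = array_label,
    p_aa = p^2, p_ab = 2 * p * maf, p_bb = maf^2,
    mu_aa = jitter_mu(band_mu[["AA"]]),
    mu_ab = jitter_mu(band_mu[["AB"]]),
    mu_bb = jitter_mu(band_mu[["BB"]]),
    v_aa = jitter_v(), v_ab = jitter_v(), v_bb = jitter_v(),
    row.names = NULL
  )
  ## constructed constraint: systematic variance below the beta bound
  for (g in c("aa", "ab", "bb")) {
    mu <- out[[paste0("mu_", g)]]
    out[[paste0("v_", g)]] <- pmin(out[[paste0("v_", g)]],
                                   0.5 * mu * (1 - mu))
  }
  structure(out, class = c("snp_generative_params", "data.frame"))
}

## internal simulation kernel: genotype index matrix (1=AA,2=AB,3=BB) and
## AF matrix under relative extra error r (V_T = V_S / (1 - r))
sim_kernel <- function(params, n_arrays, r) {
  M <- nrow(params)
  u <- matrix(stats::runif(M * n_arrays), M, n_arrays)
  ## per-row cumulative genotype probabilities recycle down columns
  g <- 1L + (u > params$p_aa) + (u > params$p_aa + params$p_ab)
  mu_all <- cbind(params$mu_aa, params$mu_ab, params$mu_bb)
  v_all <- cbind(params$v_aa, params$v_ab, params$v_bb) / (1 - r)
  idx <- cbind(as.vector(row(g)), as.vector(g))
  sh <- beta_shapes_clamped(mu_all[idx], v_all[idx])
  lam <- matrix(stats::rbeta(M * n_arrays, sh$alpha, sh$beta), M, n_arrays)
  list(g = g, lam = lam, n_clamped = sh$n_clamped)
}

## internal: per-array QI vector for one simulated replication, with the
## generating (mu_G, sqrt(V_S,G)) as the standardization reference
sim_qi <- function(params, n_arrays, r, index_kind, summary_kind, rho) {
  k <- sim_kernel(params, n_arrays, r)
  sd_all <- cbind(sqrt(params$v_aa), sqrt(params$v_ab), sqrt(params$v_bb))
  if (index_kind == "nearest_mean") {
    q <- nearest_mean_q(
      k$lam,
      mu = list(params$mu_aa, params$mu_ab, params$mu_bb),
      sdv = list(sd_all[, 1], sd_all[, 2], sd_all[, 3])
    )
  } else {
    mu_all <- cbind(params$mu_aa, params$mu_ab, params$mu_bb)
    idx <- cbind(as.vector(row(k$g)), as.vector(k$g))
    q <- matrix(abs(as.vector(k$lam) - mu_all[idx]) / sd_all[idx],
                nrow(k$lam), ncol(k$lam))
  }
  apply(q, 2L, summarize_qi, summary_kind = summary_kind, rho = rho)
}

#' Simulate genotype and allele-frequency matrices
#'
#' One simulated genotyping experiment: per SNP the genotype counts over
#' the `n_arrays` arrays follow a multinomial with the SNP's
#' Hardy-Weinberg cell probabilities (drawn as iid per-array genotypes,
#' which realizes multinomial counts with an exchangeable assignment), and
#' each cell's individual-level AF is beta-distributed within its genotype
#' band. The relative extra error `r = V_E / V_T` inflates the band
#' variance to `V_T = V_S / (1 - r)` — the unique relation consistent with
#' a fixed systematic component V_S — while leaving band means untouched,
#' so poor quality widens the three AF bands without shifting them.
#'
#' @param params `snp_generative_params` from [synth_population()].
#' @param n_arrays number of arrays (samples).
#' @param r relative extra error in \[0, 1).
#' @param seed optional integer seed.
#' @return List with `genotypes` ([genotype_matrix()]) and `af`
#'   ([af_matrix()]).
#' @export
simulate_arrays <- function(params, n_arrays, r = 0, seed = NULL) {
  stopifnot(inherits(params, "snp_generative_params"), n_arrays >= 2L,
            r >= 0, r < 1)
  if (!is.null(seed)) set.seed(seed)
  k <- sim_kernel(params, n_arrays, r)
  if (k$n_clamped > 0L) {
    warning(sprintf("%d simulated cell(s) required variance clamping at the beta bound",
                    k$n_clamped))
  }
  sample_ids <- sprintf("ARR%04d", seq_len(n_arrays))
  calls <- matrix(c("AA", "AB", "BB")[k$g], nrow(params), n_arrays)
  ann <- params[, c("snp_id", "chromosome", "position_bp", "array_label")]
  lam <- pmin(pmax(k$lam, 0), 1)
  list(genotypes = genotype_matrix(calls, ann, sample_ids),
       af = af_matrix(lam, ann, sample_ids))
}

#' AF reference holding a simulation's generating parameters
#'
#' Packages the generating band means and systematic SDs of a synthetic
#' population as an `af_reference`, the standardization reference used in
#' the detection-rate experiment (isolating index behavior from
#' reference-estimation noise).
#'
#' @param params `snp_generative_params`.
#' @param n nominal per-cell sample count recorded in the reference.
#' @return An `af_reference`.
#' @export
simulation_af_reference <- function(params, n = 1000L) {
  stopifnot(inherits(params, "snp_generative_params"))
  rows <- lapply(c(AA = "aa", AB = "ab", BB = "bb"), function(g) {
    data.frame(snp_id = params$snp_id, genotype = NA_character_,
               mean = params[[paste0("mu_", g)]],
               sd = sqrt(params[[paste0("v_", g)]]), n = n,
               chromosome = params$chromosome,
               position_bp = params$position_bp,
               array_label = params$array_label, row.names = NULL)
  })
  for (g in names(rows)) rows[[g]]$genotype <- g
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  af_reference_from_params(tab, population_label = "synthetic")
}

#' Simulation configuration
#'
#' Bundles and validates the design of a detection-rate experiment.
#'
#' @param n_arrays arrays per replication (default 100).
#' @param n_snps SNPs per array (default 690, the 100K-scale chromosome;
#'   6396 for the 500K scale).
#' @param r_grid ascending grid of relative extra errors starting at 0
#'   (default 0 to 0.6 by 0.025).
#' @param n_replications replications per grid point (default 1000).
#' @param n_null_replications replications pooled for the null thresholds
#'   (default `n_replications`).
#' @param rho winsorization quantile (default 0.95).
#' @param index_kind `"nearest_mean"` (Q2, default) or `"genotype_based"`
#'   (Q1).
#' @param summary_kind array-level summary (default `"winsorized_mean"`).
#' @param levels confidence levels (default 0.95, 0.975, 0.99).
#' @param threshold_mode `"global"` (one threshold per level from the
#'   pooled null runs, mimicking a fixed reference database; default) or
#'   `"per_replication"` (a fresh null replication per test replication).
#' @param seed integer seed for the whole experiment.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_arrays = 100L, n_snps = 690L,
                              r_grid = seq(0, 0.6, by = 0.025),
                              n_replications = 1000L,
                              n_null_replications = n_replications,
                              rho = 0.95, index_kind = "nearest_mean",
                              summary_kind = "winsorized_mean",
                              levels = c(0.95, 0.975, 0.99),
                              threshold_mode = c("global", "per_replication"),
                              seed = 1L) {
  index_kind <- match.arg(index_kind, c("nearest_mean", "genotype_based"))
  summary_kind <- match.arg(summary_kind, SUMMARY_KINDS)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(n_arrays >= 2L, all(r_grid >= 0), all(r_grid < 1),
            !is.unsorted(r_grid), r_grid[1] == 0,
            n_replications >= 1L, rho > 0, rho < 1,
            all(levels > 0), all(levels < 1))
  structure(list(n_arrays = as.integer(n_arrays), n_snps = as.integer(n_snps),
                 r_grid = r_grid, n_replications = as.integer(n_replications),
                 n_null_replications = as.integer(n_null_replications),
                 rho = rho, index_kind = index_kind,
                 summary_kind = summary_kind, levels = sort(levels),
                 threshold_mode = threshold_mode, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Detection-rate experiment
#'
#' The power study of the confidence-interval detector. Stage 1 simulates
#' good-quality data (r = 0), pools the array-level quality indices over
#' the null replications, and takes their level-quantiles as upper
#' confidence limits. Stage 2, for each relative extra error r in the
#' grid, simulates fresh replications, flags arrays whose QI strictly
#' exceeds the threshold, and reports the mean and SD over replications of
#' the flagged proportion per (r, level). At r = 0 the mean rate is the
#' false-detection rate (about 1 - level); it rises along an S-shaped
#' curve as r grows.
#'
#' @param config `simulation_config`.
#' @param params `snp_generative_params`; defaults to
#'   [synth_population()] with `config$n_snps` SNPs.
#' @return A `detection_curve` data frame (`r`, `level`, `mean_rate`,
#'   `sd_rate`, `n_replications`) with the null `thresholds` and `config`
#'   as attributes.
#' @export
detection_rate_experiment <- function(config, params = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  if (is.null(params)) params <- synth_population(config$n_snps)
  stopifnot(inherits(params, "snp_generative_params"))
  ## warn once per r about beta-bound clamping (deterministic in params, r)
  for (r in config$r_grid) {
    mu <- c(params$mu_aa, params$mu_ab, params$mu_bb)
    vt <- c(params$v_aa, params$v_ab, params$v_bb) / (1 - r)
    n_over <- sum(vt >= mu * (1 - mu))
    if (n_over > 0L) {
      warning(sprintf("r = %g: %d SNP band(s) exceed the beta variance bound and will be clamped",
                      r, n_over))
    }
  }
  one_qi <- function(r) sim_qi(params, config$n_arrays, r,
                               config$index_kind, config$summary_kind,
                               config$rho)
  thresholds <- NULL
  if (config$threshold_mode == "global") {
    pool <- unlist(lapply(seq_len(config$n_null_replications),
                          function(i) one_qi(0)))
    thresholds <- qi_quantile(pool, config$levels)
    names(thresholds) <- format(config$levels)
  }
  out <- vector("list", length(config$r_grid))
  for (j in seq_along(config$r_grid)) {
    r <- config$r_grid[j]
    rates <- matrix(NA_real_, config$n_replications, length(config$levels))
    for (rep in seq_len(config$n_replications)) {
      thr <- thresholds
      if (config$threshold_mode == "per_replication") {
        thr <- qi_quantile(one_qi(0), config$levels)
      }
      qi <- one_qi(r)
      rates[rep, ] <- vapply(seq_along(config$levels),
                             function(l) mean(qi > thr[l]), numeric(1))
    }
    out[[j]] <- data.frame(r = r, level = config$levels,
                           mean_rate = colMeans(rates),
                           sd_rate = apply(rates, 2L, stats::sd),
                           n_replications = config$n_replications,
                           row.names = NULL)
  }
  structure(do.call(rbind, out), class = c("detection_curve", "data.frame"),
            thresholds = thresholds, config = config)
}
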