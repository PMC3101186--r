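test_that("genotype-based q is the standardized distance to the called band", {
  af <- toy_af(matrix(c(0.5, 0.7, NA), 1, 3))
  geno <- toy_genotypes(matrix(c("AB", "AB", "AB"), 1, 3))
  ref <- toy_reference(1L)
  q <- snp_qi_genotype(af, geno, ref)
  expect_equal(q$q[1, 1], 0)                 # lambda equals mu_AB
  expect_equal(q$q[1, 2], 2.0)               # |0.7 - 0.5| / 0.1
  expect_true(is.na(q$q[1, 3]))              # missing AF

  geno_nc <- toy_genotypes(matrix(c("NC", "AB", "AB"), 1, 3))
  q_nc <- snp_qi_genotype(af, geno_nc, ref)
  expect_true(is.na(q_nc$q[1, 1]))           # no-call gives missing q
  expect_equal(q_nc$index_kind, "genotype_based")
})

test_that("nearest-mean q picks the closest band and breaks ties conservatively", {
  ref <- toy_reference(1L)
  q <- snp_qi_nearest(toy_af(matrix(0.9, 1, 1)), ref)
  expect_equal(q$q[1, 1], 1.0)               # nearest AA: |0.9-0.95|/0.05

  ## exactly midway between AA (sd 0.05) and AB (sd 0.1): the smaller q wins
  mid <- (0.95 + 0.5) / 2
  q_tie <- snp_qi_nearest(toy_af(matrix(mid, 1, 1)), ref)
  expect_equal(q_tie$q[1, 1], abs(mid - 0.5) / 0.1)

  ## ineligible cells are excluded from the argmin
  ref_part <- toy_reference(1L)
  ref_part$eligible[ref_part$genotype == "AA"] <- FALSE
  q_no_aa <- snp_qi_nearest(toy_af(matrix(0.9, 1, 1)), ref_part)
  expect_equal(q_no_aa$q[1, 1], abs(0.9 - 0.5) / 0.1)
})

test_that("nearest-mean q never exceeds genotype-based q at equal sigmas", {
  ref <- toy_reference(1L, sdv = c(AA = 0.07, AB = 0.07, BB = 0.07))
  grid <- seq(0.001, 0.999, length.out = 401)
  af <- toy_af(matrix(grid, 1, length(grid)))
  for (g in c("AA", "AB", "BB")) {
    geno <- toy_genotypes(matrix(g, 1, length(grid)))
    q1 <- snp_qi_genotype(af, geno, ref)$q
    q2 <- snp_qi_nearest(af, ref)$q
    expect_true(all(q2 <= q1 + 1e-12))
  }
})

test_that("q is invariant under joint location-scale change of (lambda, mu, sigma)", {
  set.seed(31)
  lam <- runif(50)
  mu <- runif(50)
  sdv <- runif(50, 0.02, 0.2)
  a <- 0.35; b <- 0.21
  expect_equal(abs(lam - mu) / sdv,
               abs((a * lam + b) - (a * mu + b)) / (a * sdv),
               tolerance = 1e-12)
})

test_that("winsorized mean matches the sort-based oracle on random vectors", {
  set.seed(77)
  for (i in 1:300) {
    n <- sample(10:1000, 1)
    x <- rlnorm(n, meanlog = runif(1, -1, 1), sdlog = runif(1, 0.05, 1))
    rho <- sample(c(0.95, 0.975, 0.99, runif(1, 0.5, 0.999)), 1)
    expect_equal(winsorized_mean(x, rho), oracle_winsorized_mean(x, rho),
                 tolerance = 1e-12)
  }
  expect_equal(winsorized_mean(rep(3.2, 40), 0.95), 3.2)  # constant invariance
})

test_that("summary kinds obey their ordering and constant invariances", {
  set.seed(13)
  x <- rlnorm(500)
  for (rho in c(0.9, 0.95, 0.99)) {
    w <- winsorized_mean(x, rho)
    expect_lte(w, mean(x))
    expect_lte(snpqc:::trimmed_mean_upper(x, rho), w)
  }
  ## winsorized mean nondecreasing in rho
  rhos <- seq(0.5, 0.999, length.out = 30)
  ws <- vapply(rhos, function(r) winsorized_mean(x, r), numeric(1))
  expect_true(all(diff(ws) >= -1e-12))
  expect_equal(snpqc:::summarize_qi(c(1, 2, 3), "median", 0.95), 2)
})

test_that("array_qi summarizes per chromosome and genome with the min-SNP rule", {
  set.seed(5)
  n_snp <- 80
  chrom <- rep(c("1", "2"), each = n_snp / 2)
  af <- toy_af(matrix(runif(n_snp * 3), n_snp, 3), chromosome = chrom)
  ref <- toy_reference(n_snp)
  ref$chromosome <- rep(chrom, each = 1)[match(ref$snp_id, paste0("rs", 1:n_snp))]
  sq <- snp_qi_nearest(af, ref)
  qt <- array_qi(sq, rho = 0.95, min_snps = 30L)
  expect_setequal(unique(qt$scope), c("GENOME", "1", "2"))
  genome <- qt[qt$scope == "GENOME", ]
  expect_equal(genome$n_snps_used, rep(n_snp, 3))
  expect_equal(genome$qi_value,
               unname(apply(sq$q, 2, oracle_winsorized_mean, rho = 0.95)),
               tolerance = 1e-12)
  ## per-chromosome scopes vanish when they fall under min_snps
  warns <- capture_warnings(qt2 <- array_qi(sq, min_snps = 50L))
  expect_match(warns, "skipped", all = TRUE)
  expect_equal(unique(qt2$scope), "GENOME")
})

test_that("merged-array QI pools SNP-level distances, not part-level indices", {
  set.seed(9)
  mk_part <- function(n, offset, label) {
    ann <- data.frame(snp_id = paste0("p", offset, "_", seq_len(n)),
                      chromosome = "1", position_bp = seq_len(n) + offset,
                      array_label = label)
    q <- matrix(rlnorm(n * 4), n, 4, dimnames = list(ann$snp_id, paste0("S", 1:4)))
    snpqc:::new_snp_qi_matrix(q, ann, paste0("S", 1:4), "nearest_mean")
  }
  p1 <- mk_part(690, 0, "Nsp")
  p2 <- mk_part(6396, 10000, "Sty")
  merged <- merge_array_qi(list(p1, p2), scopes = "genome")
  expect_equal(unique(merged$n_snps_used), 690L + 6396L)
  expect_equal(unique(merged$array_label), "Merge")
  pooled <- rbind(p1$q, p2$q)
  expect_equal(merged$qi_value,
               unname(apply(pooled, 2, oracle_winsorized_mean, rho = 0.95)),
               tolerance = 1e-12)

  ## identical q multisets in both parts leave the pooled index essentially
  ## unchanged (the interpolated quantile of the doubled multiset can move
  ## by at most one order-statistic gap)
  p2b <- mk_part(690, 20000, "Sty")
  p2b$q <- p1$q
  rownames(p2b$q) <- p2b$annotation$snp_id
  m2 <- merge_array_qi(list(p1, p2b), scopes = "genome")
  q1 <- array_qi(p1, scopes = "genome")
  expect_equal(m2$qi_value, q1$qi_value, tolerance = 0.01)

  ## overlapping SNP ids across parts are rejected
  expect_error(merge_array_qi(list(p1, p1)), "overlapping snp_id")
})

test_that("genotype call rate counts non-missing calls per scope", {
  g <- toy_genotypes(matrix(c("AA", "AB", "BB", "AB"), 2, 2))
  expect_equal(compute_gcr(g)$gcr, rep(1, 2 + 2))  # GENOME + chromosome scope

  g2 <- toy_genotypes(matrix(c("AA", "NC", "BB", "AB"), 4, 1))
  gcr <- compute_gcr(g2)
  expect_equal(gcr$gcr[gcr$scope == "GENOME"], 0.75)

  g3 <- toy_genotypes(matrix("NC", 3, 2))
  expect_equal(compute_gcr(g3)$gcr, rep(0, 4))
})
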