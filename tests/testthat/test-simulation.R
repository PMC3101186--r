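test_that("beta moment matching reproduces the target moments exactly", {
  p <- beta_moment_params(0.5, 0.05)
  expect_equal(p$alpha, 2)                       # Beta(2,2): mean 1/2, var 1/20
  expect_equal(p$beta, 2)
  u <- beta_moment_params(0.5, 1 / 12)
  expect_equal(u$alpha, 1)                       # uniform
  expect_equal(u$beta, 1)

  set.seed(19)
  for (i in 1:500) {
    mu <- runif(1, 0.01, 0.99)
    v <- runif(1, 1e-6, 0.99) * mu * (1 - mu)
    sh <- beta_moment_params(mu, v)
    m <- sh$alpha / (sh$alpha + sh$beta)
    vv <- sh$alpha * sh$beta /
      ((sh$alpha + sh$beta)^2 * (sh$alpha + sh$beta + 1))
    expect_equal(m, mu, tolerance = 1e-12)
    expect_equal(vv, v, tolerance = 1e-12)
  }

  expect_warning(cl <- beta_moment_params(0.5, 0.3), "clamped")
  vcl <- cl$alpha * cl$beta /
    ((cl$alpha + cl$beta)^2 * (cl$alpha + cl$beta + 1))
  expect_equal(vcl, 0.99 * 0.25, tolerance = 1e-12)
})

test_that("synthetic population follows Hardy-Weinberg and the beta bound", {
  params <- synth_population(500, seed = 6)
  expect_equal(params$p_aa + params$p_ab + params$p_bb, rep(1, 500),
               tolerance = 1e-12)
  ## MAF = 0.5 and 0.1 closed forms
  p5 <- synth_population(1, maf_range = c(0.5, 0.5), seed = 1)
  expect_equal(unlist(p5[, c("p_aa", "p_ab", "p_bb")], use.names = FALSE),
               c(0.25, 0.5, 0.25))
  p1 <- synth_population(1, maf_range = c(0.1, 0.1), seed = 1)
  expect_equal(unlist(p1[, c("p_aa", "p_ab", "p_bb")], use.names = FALSE),
               c(0.81, 0.18, 0.01))
  for (g in c("aa", "ab", "bb")) {
    mu <- params[[paste0("mu_", g)]]
    expect_true(all(params[[paste0("v_", g)]] < mu * (1 - mu)))
  }
  expect_error(synth_population(10, maf_range = c(0, 0.7)), "maf_range")
})

test_that("simulated genotype frequencies and AF moments match the model", {
  params <- synth_population(40, seed = 10)
  sim <- simulate_arrays(params, n_arrays = 100, r = 0, seed = 11)
  ## every array gets exactly one genotype per SNP, so counts sum to N
  expect_true(all(sim$genotypes$calls %in% c("AA", "AB", "BB")))
  expect_equal(rowSums(!is.na(sim$genotypes$calls)), rep(100, 40),
               ignore_attr = TRUE)
  expect_true(all(sim$af$af >= 0 & sim$af$af <= 1))

  ## per-(SNP, genotype) empirical mean and variance vs generating values:
  ## 10,000 draws from one band at r = 0 and r = 0.5
  one <- synth_population(1, seed = 12)
  for (r in c(0, 0.5)) {
    set.seed(100 + r * 10)
    k <- snpqc:::sim_kernel(one[rep(1, 10000), , drop = FALSE], 1, r)
    lam <- k$lam[k$g == 2]                      # heterozygous band
    n <- length(lam)
    vt <- one$v_ab / (1 - r)
    expect_lt(abs(mean(lam) - one$mu_ab), 4 * sqrt(vt / n))
    ## SE of a sample variance ~ vt * sqrt(2/(n-1)) under near-normality
    expect_lt(abs(var(lam) - vt), 4 * vt * sqrt(2 / (n - 1)))
  }
})

test_that("r = 0.5 doubles the band variance (V_T = V_S / (1 - r))", {
  expect_equal(0.0015 / (1 - 0.5), 2 * 0.0015)
  expect_equal(0.0015 / (1 - 0.4), 0.0025)
})

test_that("detection curve is calibrated at r = 0 and saturates with r", {
  cfg <- simulation_config(n_snps = 690, r_grid = c(0, 0.1, 0.4),
                           n_replications = 60, n_null_replications = 60,
                           seed = 42)
  curve <- detection_rate_experiment(cfg)
  expect_true(all(curve$mean_rate >= 0 & curve$mean_rate <= 1))
  for (lv in c(0.95, 0.975, 0.99)) {
    row <- curve[curve$r == 0 & curve$level == lv, ]
    se <- sqrt(row$sd_rate^2 / row$n_replications +
                 lv * (1 - lv) / (60 * cfg$n_arrays))
    expect_lt(abs(row$mean_rate - (1 - lv)), 4 * se + 1e-3)
  }
  ## monotone in r per level, and saturated at r = 0.4
  for (lv in c(0.95, 0.975, 0.99)) {
    sub <- curve[curve$level == lv, ]
    expect_true(all(diff(sub$mean_rate) >= -0.02))
    expect_gte(sub$mean_rate[sub$r == 0.4], 0.99)
  }
})

test_that("per-replication thresholds are also calibrated at the null", {
  cfg <- simulation_config(n_snps = 200, r_grid = 0, n_replications = 80,
                           threshold_mode = "per_replication", seed = 14)
  curve <- detection_rate_experiment(cfg)
  row <- curve[curve$level == 0.95, ]
  expect_lt(abs(row$mean_rate - 0.05), 0.03)
})

test_that("winsorized-mean summary detects at least as well as the median", {
  params <- synth_population(690, seed = 33)
  run <- function(summary_kind) {
    cfg <- simulation_config(n_snps = 690, r_grid = c(0, 0.2),
                             n_replications = 60, n_null_replications = 60,
                             summary_kind = summary_kind, seed = 33)
    curve <- detection_rate_experiment(cfg, params)
    curve$mean_rate[curve$r == 0.2 & curve$level == 0.95]
  }
  expect_gte(run("winsorized_mean"), run("median"))
})

test_that("config validation rejects malformed designs", {
  expect_error(simulation_config(r_grid = c(0.1, 0.2)), "r_grid")
  expect_error(simulation_config(r_grid = c(0, 1.2)), "r_grid")
  expect_error(simulation_config(n_arrays = 1), "n_arrays")
  expect_error(detection_rate_experiment(
    structure(list(), class = "list")), "simulation_config")
})
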