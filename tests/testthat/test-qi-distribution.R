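test_that("lognormal fit recovers log-scale moments", {
  x <- c(exp(1), exp(1), exp(3))
  fit <- fit_lognormal(c(x, rep(exp(2), 7)))   # pad to n >= 10
  expect_equal(fit$n, 10L)
  fit3 <- suppressWarnings(fit_lognormal(rep(c(exp(1), exp(1), exp(3)), 4)))
  expect_equal(fit3$meanlog, 5 / 3, tolerance = 1e-12)

  set.seed(123)
  big <- rlnorm(10000, meanlog = 0.2, sdlog = 0.1)
  fb <- fit_lognormal(big)
  expect_lt(abs(fb$meanlog - 0.2), 0.004)   # 4 * sdlog / sqrt(n)
  expect_lt(abs(fb$sdlog - 0.1), 0.003)

  expect_error(fit_lognormal(rep(2, 50)), "degenerate")
  expect_error(fit_lognormal(c(rep(1, 9), -1, 2)), "positive")
  expect_error(fit_lognormal(rlnorm(5)), "at least 10")
})

test_that("KS statistic matches the CDF-difference oracle", {
  set.seed(55)
  for (i in 1:200) {
    x <- rlnorm(sample(10:80, 1), meanlog = runif(1, -1, 1),
                sdlog = runif(1, 0.1, 0.8))
    fit <- list(meanlog = runif(1, -1, 1), sdlog = runif(1, 0.1, 0.8))
    got <- ks_lognormal(x, fit)$statistic
    want <- oracle_ks_stat(log(x), function(z) pnorm(z, fit$meanlog, fit$sdlog))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("points placed at model quantiles give a near-zero KS statistic", {
  n <- 99
  fit <- list(meanlog = 0.3, sdlog = 0.2)
  x <- exp(qnorm((1:n) / (n + 1), fit$meanlog, fit$sdlog))
  expect_lte(ks_lognormal(x, fit)$statistic, 1 / (n + 1) + 1e-12)
})

test_that("plain KS with estimated parameters is conservative", {
  set.seed(202)
  rej <- replicate(1000, {
    x <- rlnorm(100, 0.1, 0.3)
    fit_lognormal(x)$ks_pvalue < 0.05
  })
  expect_lt(mean(rej), 0.05)
})

test_that("empirical limits match the quantile oracle and are monotone", {
  qt <- structure(
    data.frame(sample_id = paste0("S", 1:100), array_label = "Nsp",
               scope = "GENOME", index_kind = "nearest_mean",
               summary_kind = "winsorized_mean", rho = 0.95,
               qi_value = as.numeric(1:100), n_snps_used = 690L),
    class = c("array_qi_table", "data.frame"))
  ref <- build_qi_reference(qt, levels = c(0.95, 0.975, 0.99))
  expect_equal(ref$limit, sapply(c(0.95, 0.975, 0.99), oracle_quantile,
                                 x = as.numeric(1:100)), tolerance = 1e-12)
  expect_true(all(diff(ref$limit) >= 0))
  expect_equal(ref$mu_qi, rep(50.5, 3))

  set.seed(88)
  qt$qi_value <- rlnorm(100, 0, 1)
  for (i in 1:50) {
    lv <- runif(1, 0.5, 0.999)
    r <- build_qi_reference(qt, levels = lv)
    expect_equal(r$limit, oracle_quantile(qt$qi_value, lv), tolerance = 1e-12)
  }
})

test_that("lognormal-source limits use the closed-form quantile", {
  set.seed(3)
  qt <- structure(
    data.frame(sample_id = paste0("S", 1:30), array_label = "Nsp",
               scope = "GENOME", index_kind = "nearest_mean",
               summary_kind = "winsorized_mean", rho = 0.95,
               qi_value = rlnorm(30), n_snps_used = 690L),
    class = c("array_qi_table", "data.frame"))
  ref <- build_qi_reference(qt, levels = 0.975, source = "lognormal")
  lx <- log(qt$qi_value)
  expect_equal(ref$limit, exp(mean(lx) + qnorm(0.975) * sd(lx)),
               tolerance = 1e-12)
  ## with meanlog 0, sdlog 1 the 97.5% limit is exp(1.959964) ~ 7.0993
  expect_equal(exp(0 + qnorm(0.975) * 1), 7.0993, tolerance = 1e-4)
})

test_that("empirical and lognormal limits agree on large lognormal samples", {
  set.seed(17)
  qt <- structure(
    data.frame(sample_id = paste0("S", 1:6000), array_label = "Nsp",
               scope = "GENOME", index_kind = "nearest_mean",
               summary_kind = "winsorized_mean", rho = 0.95,
               qi_value = rlnorm(6000, -0.2, 0.25), n_snps_used = 690L),
    class = c("array_qi_table", "data.frame"))
  emp <- build_qi_reference(qt, source = "empirical")
  lnorm <- build_qi_reference(qt, source = "lognormal")
  expect_true(all(abs(emp$limit - lnorm$limit) / lnorm$limit < 0.05))
})

test_that("detector flags strictly above the limit, per array label", {
  ref <- qi_reference_from_limits(data.frame(
    array_label = "Nsp", level = c(0.95, 0.975, 0.99),
    limit = c(1.144, 1.246, 1.385)), population_label = "TWN")
  mk_qt <- function(qi) structure(
    data.frame(sample_id = "S1", array_label = "Nsp", scope = "GENOME",
               index_kind = "nearest_mean", summary_kind = "winsorized_mean",
               rho = 0.95, qi_value = qi, n_snps_used = 1000L),
    class = c("array_qi_table", "data.frame"))
  expect_true(detect_poor_arrays(mk_qt(1.521), ref)$flag)
  expect_false(detect_poor_arrays(mk_qt(0.733), ref)$flag)
  expect_false(detect_poor_arrays(mk_qt(1.144), ref)$flag)  # boundary: strict >
  expect_error(detect_poor_arrays(mk_qt(1.0), ref, level = 0.9), "no reference stratum")
})

test_that("detector flags about (1 - level) of arrays drawn from the reference", {
  set.seed(404)
  make_qt <- function(vals) structure(
    data.frame(sample_id = paste0("S", seq_along(vals)), array_label = "Nsp",
               scope = "GENOME", index_kind = "nearest_mean",
               summary_kind = "winsorized_mean", rho = 0.95,
               qi_value = vals, n_snps_used = 690L),
    class = c("array_qi_table", "data.frame"))
  ref_vals <- rlnorm(4000, 0, 0.3)
  ref <- build_qi_reference(make_qt(ref_vals))
  n_test <- 4000
  rep_tab <- detect_poor_arrays(make_qt(rlnorm(n_test, 0, 0.3)), ref, 0.95)
  p_hat <- mean(rep_tab$flag)
  se <- sqrt(0.05 * 0.95 / n_test + 0.05 * 0.95 / 4000)
  expect_lt(abs(p_hat - 0.05), 4 * se)
})

test_that("group comparisons behave at the null, under separation, and on identity", {
  id <- rlnorm(50, 0, 0.2)
  cmp_id <- compare_groups(id, id)
  expect_equal(cmp_id$p_mean, 1)
  expect_gte(cmp_id$p_ks, 0.999)   # zero KS statistic

  set.seed(66)
  a <- rlnorm(50, 0, 0.1); b <- rlnorm(50, 1, 0.1)
  expect_lt(compare_groups(a, b)$p_mean, 1e-6)
  expect_error(compare_groups(c(a, -1), b), "positive")
  expect_error(compare_groups(a[1:5], b), "at least 10")
})

test_that("all three group tests hold their size at the null", {
  set.seed(77)
  n_rep <- 1000
  rej <- matrix(NA, n_rep, 3)
  for (i in seq_len(n_rep)) {
    cmp <- compare_groups(rlnorm(40, 0, 0.3), rlnorm(40, 0, 0.3))
    rej[i, ] <- c(cmp$p_mean, cmp$p_var, cmp$p_ks) < 0.05
  }
  rates <- colMeans(rej)
  se <- sqrt(0.05 * 0.95 / n_rep)
  ## Z and F tests track alpha; the discrete two-sample KS is conservative
  expect_lt(abs(rates[1] - 0.05), 5 * se)
  expect_lt(abs(rates[2] - 0.05), 5 * se)
  expect_lte(rates[3], 0.05 + 4 * se)
})
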