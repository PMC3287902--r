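test_that("adjusted covariance and correlation reduce to the sample versions", {
  set.seed(2001)
  n <- 150
  xa <- rbinom(n, 2, 0.3)
  xb <- rbinom(n, 2, 0.4)
  expect_equal(adjusted_covariance(xa, xb), cov(xa, xb), tolerance = 1e-12)
  expect_equal(adjusted_covariance(xa, xb), adjusted_covariance(xb, xa))
  expect_equal(adjusted_covariance(rep(1, n), rep(1, n)), 0)
  expect_equal(adjusted_correlation(xa, xa), 1)
  expect_equal(adjusted_correlation(xa, 2 - xa), -1)
  expect_error(adjusted_correlation(xa, rep(0, n)),
               class = "assocpower_degenerate_snp")
  # with covariates: equals the correlation of the residuals
  z <- data.frame(a = rnorm(n))
  ra <- residualize(xa, z)
  rb <- residualize(xb, z)
  expect_equal(adjusted_correlation(xa, xb, z),
               sum(ra * rb) / sqrt(sum(ra^2) * sum(rb^2)), tolerance = 1e-12)
})

test_that("direct effect carries beta's sign and the variance-explained closed form", {
  set.seed(2002)
  n <- 5000
  x <- rbinom(n, 2, 0.5)  # var(X) ~ 0.5
  expect_equal(direct_effect(0, x, NULL, s_yy = 1), 0)
  expect_gt(direct_effect(0.7, x, NULL, s_yy = 1), 0)
  expect_lt(direct_effect(-0.7, x, NULL, s_yy = 1), 0)
  # beta = 1, var(X) = 0.5, sigma^2 = 0.5 -> h^2 = 0.5
  s_yy <- 0.5 + var(x)
  h <- direct_effect(1, x, NULL, s_yy)
  expect_equal(h^2, var(x) / s_yy, tolerance = 1e-10)
  expect_equal(h^2, 0.5, tolerance = 0.03)
  expect_error(direct_effect(1, x, NULL, s_yy = 0),
               class = "assocpower_validation_error")
})

test_that("model-implied adjusted trait variance matches simulation", {
  set.seed(2003)
  panel <- make_causal_panel(n = 400, seed = 71L)
  g <- panel$g
  model <- panel$model
  expect_equal(model_residual_variance(trait_model(error_sd = 1.3), g),
               1.3^2)
  # one causal SNP, no covariates: sigma^2 + beta^2 var(X)
  m1 <- trait_model(snp_effects = model$snp_effects[1], error_sd = 1)
  expect_equal(model_residual_variance(m1, g),
               1 + 0.3^2 * var(g$values[, 5]), tolerance = 1e-10)
  # against the empirical residual variance over replicates
  z <- simulate_covariates(400, seed = 72L)
  s_model <- model_residual_variance(model, g, z)
  y <- simulate_traits(g, z, model, n_replicates = 500, seed = 73L)
  ry <- residualize(y, z)
  s_emp <- colSums(ry^2) / (400 - 1)
  se <- sd(s_emp) / sqrt(500)
  expect_lt(abs(mean(s_emp) - s_model), 3 * se + 0.01)
})

test_that("the noncentrality parameter follows (N-1) (sum r h)^2", {
  set.seed(2004)
  # no causal SNPs: lambda = 0 and power = alpha
  g <- simulate_genotypes_independent(c(0.3, 0.2), 100, seed = 74L)
  ncp0 <- noncentrality(g, NULL, trait_model(error_sd = 1),
                        g$snps$snp_id[1])
  expect_equal(ncp0$lambda, 0)
  expect_equal(nrow(ncp0$per_causal), 0L)
  # ten weak correlations act collectively: 100x one weak correlation
  h <- 0.12
  lam10 <- noncentrality_from_effects(rep(0.1, 10), rep(h, 10), 697)
  lam1 <- noncentrality_from_effects(0.1, h, 697)
  expect_equal(lam10 / lam1, 100)
  expect_equal(lam10, (697 - 1) * h^2)
  # cumulative term equals the sum of per-causal products
  panel <- make_causal_panel(n = 300, seed = 75L)
  ncp <- noncentrality(panel$g, NULL, panel$model, panel$g$snps$snp_id[9])
  expect_equal(ncp$cumulative, sum(ncp$per_causal$product),
               tolerance = 1e-10)
  expect_true(all(abs(ncp$per_causal$r) <= 1))
  expect_gte(ncp$lambda, 0)
  # degenerate test SNP errors
  gmono <- panel$g
  gmono$values[, 1] <- 0L
  expect_error(noncentrality(gmono, NULL, panel$model,
                             gmono$snps$snp_id[1]),
               class = "assocpower_degenerate_snp")
})

test_that("lambda is invariant to trait rescaling and extends the single-SNP formula", {
  set.seed(2005)
  panel <- make_causal_panel(n = 250, seed = 76L)
  g <- panel$g
  id <- names(panel$model$snp_effects)[1]
  lam <- noncentrality(g, NULL, panel$model, id)$lambda
  scaled <- trait_model(mu = 1, snp_effects = panel$model$snp_effects * 3,
                        error_sd = 3)
  expect_equal(noncentrality(g, NULL, scaled, id)$lambda, lam,
               tolerance = 1e-10)
  # single causal SNP tested at itself: lambda = (N-1) h^2
  m1 <- trait_model(snp_effects = panel$model$snp_effects[1], error_sd = 1)
  ncp1 <- noncentrality(g, NULL, m1, id)
  s_yy <- model_residual_variance(m1, g)
  h1 <- direct_effect(m1$snp_effects[[1]], g$values[, id], NULL, s_yy)
  expect_equal(ncp1$lambda, (250 - 1) * h1^2, tolerance = 1e-10)
  expect_equal(ncp1$per_causal$r[ncp1$per_causal$snp_id == id], 1)
})

test_that("mean score statistic across replicates approaches 1 + lambda", {
  set.seed(2006)
  panel <- make_causal_panel(n = 300, seed = 77L)
  id <- names(panel$model$snp_effects)[1]
  lam <- noncentrality(panel$g, NULL, panel$model, id)$lambda
  y <- simulate_traits(panel$g, NULL, panel$model, 800, seed = 78L)
  chi2 <- vapply(seq_len(800), function(r)
    score_test(panel$g, NULL, y[, r], id)$chi2, numeric(1))
  se <- sd(chi2) / sqrt(800)
  expect_lt(abs(mean(chi2) - (1 + lam)), 3 * se)
})

test_that("analytical power is alpha at lambda 0, monotone, and matches sampling", {
  set.seed(2007)
  expect_equal(analytical_power(0, 0.05), 0.05)
  expect_equal(analytical_power(0, 0.17), 0.17)
  lams <- seq(0, 30, by = 0.5)
  expect_true(all(diff(analytical_power(lams, 0.05)) > 0))
  expect_gt(analytical_power(1000, 0.05), 1 - 1e-10)
  # Monte-Carlo oracle at the worked configuration N=697, h=0.1, lam=(N-1)h^2
  lam <- noncentrality_from_effects(rep(0.1, 10), rep(0.1, 10), 697)
  expect_equal(lam, 6.96)
  draws <- rchisq(1e5, df = 1, ncp = lam)
  mc <- mean(draws > qchisq(0.95, 1))
  expect_lt(abs(analytical_power(lam, 0.05) - mc),
            3 * sqrt(mc * (1 - mc) / 1e5))
})

test_that("simulated power is seed-deterministic and tracks analytical power", {
  set.seed(2008)
  panel <- make_causal_panel(n = 300, seed = 79L)
  id <- names(panel$model$snp_effects)[2]
  p1 <- simulated_power(panel$g, NULL, panel$model, id,
                        n_replicates = 300, seed = 80L)
  p2 <- simulated_power(panel$g, NULL, panel$model, id,
                        n_replicates = 300, seed = 80L)
  expect_identical(p1, p2)
  lam <- noncentrality(panel$g, NULL, panel$model, id)$lambda
  pa <- analytical_power(lam, 0.05)
  expect_lt(abs(p1 - pa), 3 * sqrt(pa * (1 - pa) / 300))
})

test_that("power_scan agrees with per-SNP computation and compare_power behaves", {
  set.seed(2009)
  panel <- make_causal_panel(n = 300, seed = 81L)
  ps <- power_scan(panel$g, NULL, panel$model, n_replicates = 100,
                   seed = 82L)
  expect_s3_class(ps, "power_scan")
  for (id in c(names(panel$model$snp_effects)[1], panel$g$snps$snp_id[2])) {
    ncp <- noncentrality(panel$g, NULL, panel$model, id)
    expect_equal(ps$lambda[ps$snp_id == id], ncp$lambda, tolerance = 1e-10)
  }
  expect_true(all(ps$analytical_power >= 0.05 - 1e-12))
  expect_true(all(ps$simulated_power >= 0 & ps$simulated_power <= 1))
  cmp <- compare_power(ps)
  expect_true(cmp$variance_explained_pct > 0 &&
                cmp$variance_explained_pct <= 100)
  # exact agreement gives 100%; added noise lowers the statistic
  a <- seq(0.05, 0.95, length.out = 50)
  expect_equal(compare_power(a, a)$variance_explained_pct, 100)
  noisy1 <- a + rnorm(50, sd = 0.02)
  noisy2 <- a + rnorm(50, sd = 0.2)
  expect_gt(compare_power(a, noisy1)$variance_explained_pct,
            compare_power(a, noisy2)$variance_explained_pct)
  expect_error(compare_power(a, rep(0.5, 50)),
               class = "assocpower_degenerate_input")
})

test_that("a common causal partner out-contributes a rare one at equal beta", {
  set.seed(2010)
  # common SNP1 (MAF 0.3) and rare SNP2 (MAF 0.02) in positive LD
  haps <- rbind(c(0, 0), c(1, 0), c(1, 1))
  freq <- c(0.70, 0.28, 0.02)
  g <- simulate_genotypes_ld(list(ld_block(haps, freq)), 697, seed = 83L)
  ids <- g$snps$snp_id
  beta <- 0.5
  model <- trait_model(snp_effects = setNames(c(beta, beta), ids))
  s_yy <- model_residual_variance(model, g)
  h1 <- direct_effect(beta, g$values[, 1], NULL, s_yy)
  h2 <- direct_effect(beta, g$values[, 2], NULL, s_yy)
  r12 <- adjusted_correlation(g$values[, 1], g$values[, 2])
  expect_gt(r12, 0)
  # symmetric correlation, larger variance explained by the common SNP
  expect_gt(h1, h2)
  expect_gt(r12 * h1, r12 * h2)
  # the contributions the package reports at each test SNP agree
  ncp_at_rare <- noncentrality(g, NULL, model, ids[2])
  ncp_at_common <- noncentrality(g, NULL, model, ids[1])
  contrib_common_to_rare <-
    ncp_at_rare$per_causal$product[ncp_at_rare$per_causal$snp_id == ids[1]]
  contrib_rare_to_common <-
    ncp_at_common$per_causal$product[ncp_at_common$per_causal$snp_id == ids[2]]
  expect_gt(contrib_common_to_rare, contrib_rare_to_common)
})

test_that("chance correlation threshold reproduces the 1/sqrt(N) scaling", {
  expect_equal(round(chance_correlation_threshold(697), 3), 0.088)
  expect_equal(chance_correlation_threshold(100, 0.01),
               qnorm(0.99) / 10)
  expect_gt(chance_correlation_threshold(100),
            chance_correlation_threshold(400))
})
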