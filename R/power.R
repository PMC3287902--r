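# Analytical power of the score test with multiple causal SNPs.
#
# Under the additive trait model, u^2/v at a test SNP tau follows a
# noncentral chi-square with 1 df and noncentrality
#
#   lambda = (N - 1) * ( sum_j r_tauj * h_j )^2
#
# summed over causal SNPs j, where r_tauj is the covariate-adjusted sample
# correlation between the genotype vectors at tau and j, and h_j is the
# direct effect: h_j = beta_j * sqrt(s_jj / s_YY), so h_j^2 is the
# fraction of the (covariate-adjusted) trait variance explained by SNP j.
# The cumulative term sum_j r_tauj h_j is what makes power at a test SNP
# reflect ALL correlated causal SNPs — including weakly or spuriously
# correlated distant ones (the hyper-LD effect).

#' Covariate-adjusted covariance and correlation of genotype columns
#'
#' `adjusted_covariance()` returns `<rA, rB> / (N - 1)` where `rA`, `rB`
#' are the residuals of the columns after regression on the covariates;
#' with no covariates this is the ordinary sample covariance.
#' `adjusted_correlation()` standardizes it to `[-1, 1]`.
#'
#' @param xa,xb numeric genotype columns (length N).
#' @param covariates covariate data frame or `NULL`.
#' @return a real number (correlation in `[-1, 1]`).
#' @export
adjusted_covariance <- function(xa, xb, covariates = NULL) {
  stopifnot(length(xa) == length(xb))
  r <- residualize(cbind(a = as.numeric(xa), b = as.numeric(xb)), covariates)
  sum(r[, 1] * r[, 2]) / (length(xa) - 1L)
}

#' @rdname adjusted_covariance
#' @export
adjusted_correlation <- function(xa, xb, covariates = NULL) {
  stopifnot(length(xa) == length(xb))
  r <- residualize(cbind(a = as.numeric(xa), b = as.numeric(xb)), covariates)
  saa <- sum(r[, 1]^2)
  sbb <- sum(r[, 2]^2)
  if (saa <= 0 || sbb <= 0)
    abort_ap("zero-variance column in adjusted_correlation",
             class = "assocpower_degenerate_snp")
  max(-1, min(1, sum(r[, 1] * r[, 2]) / sqrt(saa * sbb)))
}

#' Direct effect of a causal SNP
#'
#' `h = beta * sqrt(s_xx / s_yy)` where `s_xx` is the covariate-adjusted
#' genotype variance and `s_yy` the (model-implied or empirical) adjusted
#' trait variance; `h^2` is the fraction of adjusted trait variance the
#' SNP explains directly.
#'
#' @param beta allele effect size.
#' @param x genotype column.
#' @param covariates covariate data frame or `NULL`.
#' @param s_yy adjusted trait variance, > 0.
#' @return the signed direct effect `h`.
#' @export
direct_effect <- function(beta, x, covariates = NULL, s_yy) {
  if (!is.numeric(s_yy) || s_yy <= 0)
    abort_ap("s_yy must be positive", class = "assocpower_validation_error")
  beta * sqrt(adjusted_covariance(x, x, covariates) / s_yy)
}

#' Model-implied adjusted trait variance
#'
#' The variance of the covariate-adjusted trait under a [trait_model()]:
#' `error_sd^2 + t(beta) S beta`, with `S` the matrix of covariate-
#' adjusted genotype covariances among the causal SNPs. No independence
#' among causal SNPs is assumed — their (adjusted) sample covariances
#' enter in full.
#'
#' @param model a [trait_model()].
#' @param g a [genotype_matrix()] containing the model's causal SNPs.
#' @param covariates covariate data frame or `NULL`.
#' @return the adjusted trait variance `s_yy`.
#' @export
model_residual_variance <- function(model, g, covariates = NULL) {
  causal <- model_causal(model, g)
  if (length(causal$ids) == 0L) return(model$error_sd^2)
  x <- impute_genotypes(g$values[, snp_index(g, causal$ids), drop = FALSE])
  r <- residualize(x, covariates)
  s <- crossprod(r) / (n_individuals(g) - 1L)
  model$error_sd^2 + drop(t(causal$beta) %*% s %*% causal$beta)
}

#' Noncentrality parameter from per-causal contributions
#'
#' The primitive behind [noncentrality()]:
#' `lambda = (n - 1) * (sum(r * h))^2`. Exposed so that worked examples
#' (e.g. ten causal SNPs each with r = 0.1 and equal h) can be evaluated
#' directly.
#'
#' @param r adjusted correlations between the test SNP and each causal SNP.
#' @param h direct effects of the causal SNPs (same length).
#' @param n sample size N.
#' @return the noncentrality parameter `lambda`.
#' @export
noncentrality_from_effects <- function(r, h, n) {
  stopifnot(length(r) == length(h), n > 1, all(abs(r) <= 1 + 1e-12))
  (n - 1) * sum(r * h)^2
}

#' Noncentrality breakdown at a test SNP
#'
#' Computes `lambda = (N - 1) * (sum_j r_tauj h_j)^2` over the model's
#' causal SNPs and reports the per-causal-SNP contributions `r_tauj * h_j`
#' — the table that diagnoses how much of the power at a test SNP comes
#' from each (possibly distant) causal SNP. `h_j` uses the model-implied
#' adjusted trait variance ([model_residual_variance()]), i.e. the true
#' simulation-model effect sizes.
#'
#' @inheritParams model_residual_variance
#' @param test_snp id of the test SNP.
#' @return object of class `noncentrality`: list with `test_snp`, `n`,
#'   `s_yy`, `per_causal` (data frame: `snp_id`, `r`, `h`, `product`),
#'   `cumulative` (`sum(r*h)`) and `lambda`.
#' @export
noncentrality <- function(g, covariates = NULL, model, test_snp) {
  n <- n_individuals(g)
  causal <- model_causal(model, g)
  s_yy <- model_residual_variance(model, g, covariates)
  xt <- impute_genotypes(g$values[, snp_index(g, test_snp), drop = FALSE])
  rt <- residualize(drop(xt), covariates)
  stt <- sum(rt^2) / (n - 1)
  if (stt <= 0)
    abort_ap("test SNP '%s' is constant after covariate adjustment",
             test_snp, class = "assocpower_degenerate_snp")
  if (length(causal$ids) == 0L) {
    per <- data.frame(snp_id = character(0), r = numeric(0), h = numeric(0),
                      product = numeric(0), stringsAsFactors = FALSE)
  } else {
    xc <- impute_genotypes(g$values[, snp_index(g, causal$ids),
                                    drop = FALSE])
    rc <- residualize(xc, covariates)
    sjj <- colSums(rc^2) / (n - 1)
    r <- drop(crossprod(rc, rt)) / (n - 1) / sqrt(sjj * stt)
    h <- causal$beta * sqrt(sjj / s_yy)
    per <- data.frame(snp_id = causal$ids, r = unname(r), h = unname(h),
                      product = unname(r * h), stringsAsFactors = FALSE)
  }
  cumulative <- sum(per$product)
  structure(list(test_snp = test_snp, n = n, s_yy = s_yy,
                 per_causal = per, cumulative = cumulative,
                 lambda = noncentrality_from_effects(per$r, per$h, n)),
            class = "noncentrality")
}

#' @export
print.noncentrality <- function(x, ...) {
  cat(sprintf("noncentrality at %s (N = %d): lambda = %.4f\n",
              x$test_snp, x$n, x$lambda))
  cat(sprintf("  cumulative effect sum(r*h) = %.4f over %d causal SNP(s)\n",
              x$cumulative, nrow(x$per_causal)))
  if (nrow(x$per_causal) > 0) {
    ord <- order(-abs(x$per_causal$product))
    print(utils::head(x$per_causal[ord, ], 10), row.names = FALSE)
  }
  invisible(x)
}

#' Analytical power of the 1-df score test
#'
#' Upper-tail probability that a noncentral chi-square(1 df, `lambda`)
#' variate exceeds the central chi-square(1 df) critical value at level
#' `alpha`. `lambda = 0` returns exactly `alpha`.
#'
#' @param lambda noncentrality parameter(s), >= 0.
#' @param alpha nominal level in (0, 1).
#' @return rejection probability in `[alpha, 1]`.
#' @export
analytical_power <- function(lambda, alpha = 0.05) {
  stopifnot(all(lambda >= 0), alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
}

#' Simulated power at a test SNP
#'
#' Fraction of replicate traits (drawn by [simulate_traits()] under the
#' model, genotypes fixed) for which the score test at `test_snp` rejects
#' at level `alpha`.
#'
#' @inheritParams noncentrality
#' @param test_snp id of the test SNP.
#' @param n_replicates number of replicate trait vectors (default 100).
#' @param alpha nominal level.
#' @param seed optional seed (deterministic given seed).
#' @return rejection rate in `[0, 1]`.
#' @export
simulated_power <- function(g, covariates = NULL, model, test_snp,
                            n_replicates = 100L, alpha = 0.05, seed = NULL) {
  stopifnot(n_replicates >= 1)
  y <- simulate_traits(g, covariates, model, n_replicates, seed = seed)
  res <- score_tests_replicates(g, covariates, y, test_snp)
  mean(res$p < alpha)
}

# Score tests of one SNP against many trait replicates, vectorized.
# Returns data.frame(chi2, p) with one row per replicate.
score_tests_replicates <- function(g, covariates, y, snp_id) {
  n <- n_individuals(g)
  qz <- design_qr(covariates, n)
  x <- drop(impute_genotypes(g$values[, snp_index(g, snp_id),
                                      drop = FALSE]))
  rx <- qr.resid(qz, x)
  ssx <- sum(rx^2)
  if (ssx <= 1e-12 * max(1, sum(x^2)))
    abort_ap("SNP '%s' is constant after covariate adjustment", snp_id,
             class = "assocpower_degenerate_snp")
  ry <- qr.resid(qz, as.matrix(y))
  s_yy <- colSums(ry^2) / (n - 1)
  u <- drop(crossprod(ry, rx))
  chi2 <- u^2 / (s_yy * ssx)
  data.frame(chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Analytical and simulated power across a panel
#'
#' For each test SNP computes the noncentrality parameter, the analytical
#' power and (optionally) the simulated power from a shared set of
#' replicate traits — the same replicates are used for every SNP, mirroring
#' the replicate-phenotype design. Fully vectorized; suitable for panels
#' of thousands of SNPs.
#'
#' @inheritParams noncentrality
#' @param snp_ids optional subset of test SNPs; default all non-degenerate.
#' @param alpha nominal level.
#' @param n_replicates replicate traits for simulated power; 0 skips the
#'   simulation.
#' @param seed optional seed for the replicate traits.
#' @param r_threshold correlation level used for the reported count of
#'   contributing causal SNPs (`|r| > r_threshold`).
#' @return data frame of class `power_scan`: `snp_id`, `maf`, `lambda`,
#'   `cumulative_effect`, `n_contributing_causal`, `analytical_power`,
#'   `simulated_power`.
#' @export
power_scan <- function(g, covariates = NULL, model, snp_ids = NULL,
                       alpha = 0.05, n_replicates = 100L, seed = NULL,
                       r_threshold = 0.1) {
  n <- n_individuals(g)
  idx <- if (is.null(snp_ids)) seq_len(n_snps(g)) else snp_index(g, snp_ids)
  qz <- design_qr(covariates, n)
  x <- impute_genotypes(g$values[, idx, drop = FALSE])
  rx <- qr.resid(qz, x)
  ssx <- colSums(rx^2)
  keep <- ssx > 1e-12 * pmax(1, colSums(x^2))
  if (any(!keep))
    message(sprintf("power_scan: skipping %d degenerate SNP(s)", sum(!keep)))
  idx <- idx[keep]
  rx <- rx[, keep, drop = FALSE]
  ssx <- ssx[keep]

  causal <- model_causal(model, g)
  s_yy <- model_residual_variance(model, g, covariates)
  if (length(causal$ids) > 0) {
    xc <- impute_genotypes(g$values[, snp_index(g, causal$ids),
                                    drop = FALSE])
    rc <- qr.resid(qz, xc)
    sjj <- colSums(rc^2) / (n - 1)
    h <- causal$beta * sqrt(sjj / s_yy)
    # adjusted correlations: (M x J)
    rmat <- crossprod(rx, rc) / outer(sqrt(ssx), sqrt(colSums(rc^2)))
    cumulative <- drop(rmat %*% h)
    n_contrib <- rowSums(abs(rmat) > r_threshold)
  } else {
    cumulative <- rep(0, length(idx))
    n_contrib <- rep(0L, length(idx))
  }
  lambda <- (n - 1) * cumulative^2
  out <- data.frame(
    snp_id = g$snps$snp_id[idx],
    maf = g$snps$maf[idx],
    lambda = lambda,
    cumulative_effect = cumulative,
    n_contributing_causal = n_contrib,
    analytical_power = analytical_power(lambda, alpha),
    simulated_power = NA_real_,
    stringsAsFactors = FALSE
  )
  if (n_replicates > 0) {
    y <- simulate_traits(g, covariates, model, n_replicates, seed = seed)
    ry <- qr.resid(qz, y)
    s_rep <- colSums(ry^2) / (n - 1)
    u <- crossprod(rx, ry)                      # M x R
    chi2 <- sweep(u^2, 2L, s_rep, "/") / ssx
    crit <- stats::qchisq(1 - alpha, df = 1)
    out$simulated_power <- rowMeans(chi2 > crit)
  }
  attr(out, "alpha") <- alpha
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("power_scan", "data.frame")
  out
}

#' @export
print.power_scan <- function(x, ...) {
  cat(sprintf("power_scan: %d SNPs, alpha = %g, %d replicate(s)\n",
              nrow(x), attr(x, "alpha"), attr(x, "n_replicates")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' @export
plot.power_scan <- function(x, ...) {
  plot(x$analytical_power, x$simulated_power,
       xlab = "analytical power", ylab = "simulated power",
       xlim = c(0, 1), ylim = c(0, 1), pch = 3, ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Agreement between analytical and simulated power
#'
#' Squared Pearson correlation between the analytical and simulated power
#' across SNPs, as a percentage (the variance in simulated power explained
#' by the analytical power), plus a per-SNP residual table.
#'
#' @param analytical,simulated numeric vectors of equal length (>= 2), or
#'   a `power_scan` data frame given as `analytical` alone.
#' @return list with `variance_explained_pct` and `residuals` (data frame
#'   with `analytical`, `simulated`, `residual`).
#' @export
compare_power <- function(analytical, simulated = NULL) {
  if (is.data.frame(analytical) && is.null(simulated)) {
    simulated <- analytical$simulated_power
    analytical <- analytical$analytical_power
  }
  stopifnot(length(analytical) == length(simulated),
            length(analytical) >= 2)
  if (stats::sd(analytical) == 0 || stats::sd(simulated) == 0)
    abort_ap("constant power vector; variance explained undefined",
             class = "assocpower_degenerate_input")
  r2 <- stats::cor(analytical, simulated)^2
  list(variance_explained_pct = 100 * r2,
       residuals = data.frame(analytical = analytical,
                              simulated = simulated,
                              residual = simulated - analytical))
}

#' Chance-correlation threshold between independent SNPs
#'
#' Between common SNPs in linkage equilibrium the sample correlation is
#' approximately normal with mean 0 and variance 1/N, so a fraction `tail`
#' of pairs exceeds `qnorm(1 - tail) / sqrt(n)` by chance (0.088 for the
#' upper 1% tail at N = 697).
#'
#' @param n sample size.
#' @param tail upper-tail probability (default 0.01).
#' @return the correlation threshold.
#' @export
chance_correlation_threshold <- function(n, tail = 0.01) {
  stopifnot(n > 0, tail > 0, tail < 1)
  stats::qnorm(1 - tail) / sqrt(n)
}
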