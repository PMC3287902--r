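# Covariate-adjusted score tests of quantitative-trait association.
#
# For a test SNP tau with genotype vector X and trait vector Y, let rX and
# rY be the residuals of X and Y after least-squares regression on the
# design Z = (1, Z_1, ..., Z_K). The score statistic and its null variance
# estimate are
#
#   u = <rX, rY>,          v = s_YY * ||rX||^2,   s_YY = ||rY||^2 / (N - 1)
#
# and u^2 / v is referred to a chi-square distribution with 1 df. With no
# covariates this collapses to the classical (N - 1) * cor(X, Y)^2.

# Build the [1 | covariates] design matrix; factors are expanded to
# indicator columns with one level dropped. With check_rank, a
# rank-deficient design errors, naming the collinear columns.
covariate_design <- function(covariates, n, check_rank = TRUE) {
  if (is.null(covariates) || (is.data.frame(covariates) &&
                              ncol(covariates) == 0L)) {
    z <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    return(z)
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n)
    abort_ap("covariates have %d rows but %d individuals expected",
             nrow(covariates), n, class = "assocpower_validation_error")
  z <- stats::model.matrix(~ ., data = covariates)
  if (check_rank) {
    q <- qr(z)
    if (q$rank < ncol(z)) {
      dropped <- colnames(z)[q$pivot[(q$rank + 1L):ncol(z)]]
      abort_ap("collinear covariate column(s): %s",
               paste(dropped, collapse = ", "),
               class = "assocpower_rank_error")
    }
  }
  z
}

# Mean-impute missing genotype entries per SNP (column), keeping N fixed.
impute_genotypes <- function(x) {
  if (!anyNA(x)) return(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  for (j in which(colSums(is.na(x)) > 0)) {
    xj <- x[, j]
    m <- mean(xj, na.rm = TRUE)
    if (is.nan(m))
      abort_ap("column %d is entirely missing", j,
               class = "assocpower_degenerate_input")
    xj[is.na(xj)] <- m
    x[, j] <- xj
  }
  x
}

#' Residualize columns on measured covariates
#'
#' Removes from each column its least-squares projection onto the span of
#' the intercept and the covariates. The result is orthogonal to every
#' design column (to numerical tolerance) and the operation is idempotent.
#'
#' @param x numeric vector or matrix (columns residualized independently).
#' @param covariates covariate data frame, or `NULL` for intercept-only
#'   adjustment (mean-centering).
#' @return object of the same shape as `x`.
#' @export
residualize <- function(x, covariates = NULL) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  z <- covariate_design(covariates, nrow(x))
  r <- qr.resid(qr(z), x)
  if (vec) drop(r) else r
}

# qr decomposition of the design for repeated residualization.
design_qr <- function(covariates, n) qr(covariate_design(covariates, n))

#' Score test of association at a single SNP
#'
#' Computes the covariate-adjusted score statistic `u`, its variance
#' estimate `v`, the chi-square statistic `u^2/v` and an upper-tail
#' chi-square(1 df) p-value. The residual-trait sample variance `s_YY`
#' uses divisor N - 1 (so the unadjusted case reduces to
#' `(N-1) * cor(X, Y)^2`); divisor N - K - 1 is available via
#' `syy_divisor = "residual_df"`.
#'
#' @param g a [genotype_matrix()].
#' @param covariates covariate data frame or `NULL`.
#' @param y numeric trait vector (one replicate).
#' @param snp_id id of the test SNP.
#' @param syy_divisor `"n_minus_1"` (default) or `"residual_df"`.
#' @return object of class `score_test`: list with `snp_id`, `u`, `v`,
#'   `chi2`, `p_value`, `n`.
#' @export
score_test <- function(g, covariates = NULL, y, snp_id,
                       syy_divisor = c("n_minus_1", "residual_df")) {
  j <- snp_index(g, snp_id)
  x <- impute_genotypes(g$values[, j, drop = FALSE])
  score_test_column(drop(x), covariates, y, snp_id,
                    syy_divisor = match.arg(syy_divisor))
}

# Core of the score test on an explicit (already imputed) genotype column.
score_test_column <- function(x, covariates, y, snp_id,
                              syy_divisor = "n_minus_1", qz = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (!all(is.finite(y)))
    abort_ap("trait vector contains non-finite values",
             class = "assocpower_validation_error")
  if (is.null(qz)) qz <- design_qr(covariates, n)
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  ssx <- sum(rx^2)
  if (ssx <= 1e-12 * max(1, sum(x^2)))
    abort_ap("SNP '%s' is constant after covariate adjustment", snp_id,
             class = "assocpower_degenerate_snp")
  div <- if (syy_divisor == "residual_df") n - qz$rank else n - 1L
  s_yy <- sum(ry^2) / div
  u <- sum(rx * ry)
  v <- s_yy * ssx
  # a trait entirely explained by the covariates carries no evidence
  degenerate_y <- s_yy <= 1e-14 * max(1, sum(y^2) / n)
  chi2 <- if (v > 0 && !degenerate_y) u^2 / v else 0
  structure(list(snp_id = snp_id, u = u, v = v, chi2 = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 n = n),
            class = "score_test")
}

#' @export
print.score_test <- function(x, ...) {
  cat(sprintf("score test at %s (N = %d)\n", x$snp_id, x$n))
  cat(sprintf("  u = %.6g, v = %.6g, u^2/v = %.4f, p = %.4g (chi-square, 1 df)\n",
              x$u, x$v, x$chi2, x$p_value))
  invisible(x)
}

#' Collapsed (burden-style) score test
#'
#' Forms the pseudo-genotype `sum_i w_i X_i` over the given SNPs and
#' applies the single-SNP score test to it — the usual way of testing
#' rare variants jointly. With a single SNP and weight 1 this reduces
#' exactly to [score_test()].
#'
#' @inheritParams score_test
#' @param snp_ids ids of the SNPs to collapse.
#' @param weights per-SNP weights (default all 1).
#' @return a `score_test` object for the pseudo-genotype.
#' @export
collapsed_score_test <- function(g, covariates = NULL, y, snp_ids,
                                 weights = NULL,
                                 syy_divisor = c("n_minus_1", "residual_df")) {
  stopifnot(length(snp_ids) >= 1)
  weights <- weights %||% rep(1, length(snp_ids))
  if (length(weights) != length(snp_ids))
    abort_ap("need one weight per SNP", class = "assocpower_validation_error")
  x <- impute_genotypes(g$values[, snp_index(g, snp_ids), drop = FALSE])
  pseudo <- drop(x %*% weights)
  score_test_column(pseudo, covariates, y,
                    sprintf("collapsed(%s)", paste(snp_ids, collapse = "+")),
                    syy_divisor = match.arg(syy_divisor))
}

#' Score-test scan over a panel
#'
#' Runs the single-SNP score test at each SNP (or a subset), skipping
#' degenerate SNPs (constant after adjustment) with a message. The
#' computation is vectorized: the design is factorized once and all
#' genotype columns are residualized together.
#'
#' @inheritParams score_test
#' @param snp_ids optional subset of SNP ids; default all.
#' @return data frame with columns `snp_id`, `chromosome`, `position_bp`,
#'   `maf`, `u`, `v`, `chi2`, `p`.
#' @export
score_scan <- function(g, covariates = NULL, y, snp_ids = NULL,
                       syy_divisor = c("n_minus_1", "residual_df")) {
  syy_divisor <- match.arg(syy_divisor)
  idx <- if (is.null(snp_ids)) seq_len(n_snps(g)) else snp_index(g, snp_ids)
  n <- n_individuals(g)
  qz <- design_qr(covariates, n)
  x <- impute_genotypes(g$values[, idx, drop = FALSE])
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  ssx <- colSums(rx^2)
  keep <- ssx > 1e-12 * pmax(1, colSums(x^2))
  if (any(!keep))
    message(sprintf("skipping %d degenerate SNP(s): %s", sum(!keep),
                    paste(utils::head(g$snps$snp_id[idx][!keep], 5),
                          collapse = ", ")))
  div <- if (syy_divisor == "residual_df") n - qz$rank else n - 1L
  s_yy <- sum(ry^2) / div
  u <- drop(crossprod(rx, ry))
  v <- s_yy * ssx
  chi2 <- ifelse(keep, u^2 / v, NA_real_)
  out <- data.frame(
    snp_id = g$snps$snp_id[idx],
    chromosome = g$snps$chromosome[idx],
    position_bp = g$snps$position_bp[idx],
    maf = g$snps$maf[idx],
    u = ifelse(keep, u, NA_real_),
    v = ifelse(keep, v, NA_real_),
    chi2 = chi2,
    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  out[keep, , drop = FALSE]
}
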