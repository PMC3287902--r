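# Hardy-Weinberg equilibrium testing and panel filtering.
#
# Default test: the exact conditional test — the distribution of the
# heterozygote count given the observed allele counts under HWE, with the
# p-value defined as the total probability of all heterozygote counts no
# more probable than the observed one. A 1-df goodness-of-fit chi-square
# (no continuity correction) is available as an option.

# Exact HWE p-value from genotype counts (n_hom_major, n_het, n_hom_minor),
# computed with the standard mid-less recurrence over heterozygote counts.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_b <- 2L * n_bb + n_ab            # minor-allele count
  if (n_b > n) {                     # orient so n_b is the rarer allele
    tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp
    n_b <- 2L * n_bb + n_ab
  }
  if (n == 0L || n_b == 0L || n_b == 2L * n) return(1)
  hets <- seq(n_b %% 2L, min(n_b, 2L * n - n_b), by = 2L)
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - n_b * (2 * n - n_b) / (2 * n)))
  probs[mid] <- 1
  # upward recurrence: P(h+2)/P(h) = 4 * n_aa(h) * n_bb(h) / ((h+2)(h+1))
  if (mid < length(hets)) for (k in mid:(length(hets) - 1L)) {
    h <- hets[k]
    haa <- (2L * n - n_b - h) / 2
    hbb <- (n_b - h) / 2
    probs[k + 1L] <- probs[k] * 4 * haa * hbb / ((h + 2) * (h + 1))
  }
  if (mid > 1L) for (k in mid:2L) {
    h <- hets[k]
    haa <- (2L * n - n_b - h) / 2
    hbb <- (n_b - h) / 2
    probs[k - 1L] <- probs[k] * h * (h - 1) / (4 * (haa + 1) * (hbb + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Chi-square HWE p-value (1 df) from genotype counts.
hwe_chisq_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1)
  expct <- n * c(p^2, 2 * p * q, q^2)
  stat <- sum((c(n_aa, n_ab, n_bb) - expct)^2 / expct)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

hwe_counts <- function(x) {
  x <- x[!is.na(x)]
  c(sum(x == 0), sum(x == 1), sum(x == 2))
}

#' Hardy-Weinberg equilibrium test for one SNP
#'
#' Tests HWE within each population separately and returns the smallest
#' per-population p-value — the quantity a per-population QC filter acts
#' on. Monomorphic (or empty) populations return p = 1 by convention.
#'
#' @param x genotype column (0/1/2, `NA` missing).
#' @param population optional vector of population labels, one per
#'   individual; `NULL` treats the sample as one population.
#' @param method `"exact"` (exact conditional test, default) or
#'   `"chisq"` (1-df goodness of fit).
#' @return smallest p-value across populations. Attribute `"per_population"`
#'   carries the named vector of per-population p-values.
#' @export
hwe_test <- function(x, population = NULL, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (is.null(population)) population <- rep("all", length(x))
  stopifnot(length(population) == length(x))
  pvals <- vapply(split(x, population), function(xi) {
    cnt <- hwe_counts(xi)
    if (sum(cnt) == 0L)
      abort_ap("no non-missing genotypes in a population",
               class = "assocpower_degenerate_input")
    if (cnt[1] + cnt[2] == 0L || cnt[2] + cnt[3] == 0L) return(1)  # monomorphic
    if (method == "exact") hwe_exact_p(cnt[1], cnt[2], cnt[3])
    else hwe_chisq_p(cnt[1], cnt[2], cnt[3])
  }, numeric(1))
  structure(min(pvals), per_population = pvals)
}

#' Filter a panel on per-population HWE p-values
#'
#' Removes every SNP whose minimum per-population HWE p-value falls below
#' `threshold` (default 1e-4, the customary exome-panel QC cut); the order
#' of the surviving SNPs is preserved.
#'
#' @param g a [genotype_matrix()].
#' @param population optional population labels (see [hwe_test()]).
#' @param threshold p-value threshold in (0, 1).
#' @inheritParams hwe_test
#' @return list with `genotypes` (filtered panel) and `removed`
#'   (character vector of removed SNP ids).
#' @export
hwe_filter <- function(g, population = NULL, threshold = 1e-4,
                       method = c("exact", "chisq")) {
  stopifnot(threshold >= 0, threshold < 1)
  method <- match.arg(method)
  p <- apply(g$values, 2L, hwe_test, population = population,
             method = method)
  drop <- p < threshold
  list(
    genotypes = if (any(drop)) g[, which(!drop)] else g,
    removed = g$snps$snp_id[drop]
  )
}
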