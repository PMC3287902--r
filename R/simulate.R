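# Simulators for genotype panels, covariates and replicate quantitative
# traits. The trait model is
#
#   Y = mu + sum_k alpha_k Z_k + sum_j beta_j X_j + eps,   eps ~ N(0, sd^2)
#
# with genotypes coded as minor-allele counts. Replicate traits redraw eps
# only: genotypes and covariates stay fixed across replicates, matching
# the replicate-phenotype design used to estimate simulated power.

#' Trait model specification
#'
#' @param mu baseline mean trait value.
#' @param covariate_effects numeric vector of covariate effects, one per
#'   expanded covariate column (factors expanded to indicators, one level
#'   dropped); may be named by column name. Use `numeric(0)` for none.
#' @param snp_effects named numeric vector: allele effect size (trait
#'   units per minor-allele copy) for each causal SNP, named by `snp_id`.
#' @param error_sd residual standard deviation, > 0.
#' @return object of class `trait_model`.
#' @export
trait_model <- function(mu = 0, covariate_effects = numeric(0),
                        snp_effects = numeric(0), error_sd = 1) {
  stopifnot(is.numeric(error_sd), length(error_sd) == 1L, error_sd > 0)
  if (length(snp_effects) > 0 && is.null(names(snp_effects)))
    abort_ap("snp_effects must be named by snp_id",
             class = "assocpower_validation_error")
  structure(list(mu = mu,
                 covariate_effects = covariate_effects,
                 snp_effects = snp_effects,
                 error_sd = error_sd),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("trait_model: mu = %g, %d covariate effect(s), %d causal SNP(s), error SD = %g\n",
              x$mu, length(x$covariate_effects), length(x$snp_effects),
              x$error_sd))
  invisible(x)
}

# Pull the model's causal ids/betas and check they exist in the panel.
model_causal <- function(model, g) {
  ids <- names(model$snp_effects)
  keep <- model$snp_effects != 0
  ids <- ids[keep]
  if (length(ids) > 0) snp_index(g, ids)  # errors if absent
  list(ids = ids, beta = unname(model$snp_effects[keep]))
}

#' Simulate independent HWE genotypes
#'
#' Each entry for SNP j is an independent Binomial(2, maf_j) draw —
#' SNPs in Hardy-Weinberg equilibrium and pairwise linkage equilibrium.
#' SNPs are placed on synthetic chromosomes by [snp_layout()].
#'
#' @param mafs vector of minor allele frequencies in `[0, 0.5]`.
#' @param n_individuals sample size N.
#' @param seed optional integer seed (restores the caller's RNG stream).
#' @param snp_ids optional ids (default `S00001`, ...).
#' @param snps_per_chromosome,spacing_bp layout parameters, see
#'   [snp_layout()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes_independent <- function(mafs, n_individuals, seed = NULL,
                                           snp_ids = NULL,
                                           snps_per_chromosome = 1000L,
                                           spacing_bp = 1e6) {
  if (any(mafs < 0 | mafs > 0.5))
    abort_ap("mafs must lie in [0, 0.5]",
             class = "assocpower_validation_error")
  stopifnot(n_individuals >= 1)
  m <- length(mafs)
  values <- with_seed(seed, matrix(
    stats::rbinom(n_individuals * m, size = 2L,
                  prob = rep(mafs, each = n_individuals)),
    nrow = n_individuals, ncol = m))
  colnames(values) <- snp_ids %||% sprintf("S%05d", seq_len(m))
  genotype_matrix(values,
                  snps = snp_layout(colnames(values), snps_per_chromosome,
                                    spacing_bp))
}

#' LD block specification
#'
#' A block is a small set of adjacent SNPs whose haplotypes are drawn
#' jointly: each individual receives two independent haplotypes per block,
#' and the genotype is their sum. Blocks are mutually independent.
#'
#' @param haplotypes 0/1 matrix, one row per haplotype, one column per SNP
#'   in the block.
#' @param freq haplotype frequencies, summing to 1.
#' @return object of class `ld_block`.
#' @export
ld_block <- function(haplotypes, freq) {
  haplotypes <- as.matrix(haplotypes)
  if (!all(haplotypes %in% c(0, 1)))
    abort_ap("haplotypes must be 0/1", class = "assocpower_validation_error")
  if (length(freq) != nrow(haplotypes) || any(freq < 0) ||
      abs(sum(freq) - 1) > 1e-8)
    abort_ap("haplotype frequencies must be nonnegative and sum to 1",
             class = "assocpower_validation_error")
  structure(list(haplotypes = haplotypes, freq = freq), class = "ld_block")
}

#' Random LD blocks via an allele-copy mechanism
#'
#' Builds `n_blocks` haplotype blocks: within a block the first SNP's
#' haplotype allele is Bernoulli(maf drawn from `maf_range`), and each
#' further SNP copies that allele with probability `copy_prob` (else draws
#' a fresh allele at its own MAF). Population haplotype frequencies are the
#' empirical frequencies of `n_haplotypes` founder haplotypes, so within-
#' block LD is genuine (expected r approximately `copy_prob` between the
#' anchor and a partner).
#'
#' @param n_blocks,block_size number and width of blocks.
#' @param n_haplotypes founder haplotypes per block.
#' @param maf_range range the per-SNP MAFs are drawn from.
#' @param copy_prob allele-copy probability controlling within-block LD.
#' @param seed optional seed.
#' @return list of [ld_block()] objects.
#' @export
random_ld_blocks <- function(n_blocks, block_size, n_haplotypes = 16L,
                             maf_range = c(0.1, 0.5), copy_prob = 0.8,
                             seed = NULL) {
  with_seed(seed, {
    lapply(seq_len(n_blocks), function(b) {
      mafs <- stats::runif(block_size, maf_range[1], maf_range[2])
      h <- matrix(0L, n_haplotypes, block_size)
      h[, 1] <- stats::rbinom(n_haplotypes, 1L, mafs[1])
      if (block_size > 1) for (s in 2:block_size) {
        copy <- stats::runif(n_haplotypes) < copy_prob
        h[, s] <- ifelse(copy, h[, 1], stats::rbinom(n_haplotypes, 1L, mafs[s]))
      }
      ld_block(h, rep(1 / n_haplotypes, n_haplotypes))
    })
  })
}

#' Simulate genotypes with LD blocks
#'
#' @param blocks list of [ld_block()] objects (a single block may be given
#'   bare). SNPs of consecutive blocks are laid out consecutively by
#'   [snp_layout()], so within-block SNPs are close and cross-block pairs
#'   may or may not be, depending on the layout spacing.
#' @inheritParams simulate_genotypes_independent
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes_ld <- function(blocks, n_individuals, seed = NULL,
                                  snp_ids = NULL,
                                  snps_per_chromosome = 1000L,
                                  spacing_bp = 1e6) {
  if (inherits(blocks, "ld_block")) blocks <- list(blocks)
  stopifnot(length(blocks) > 0, all(vapply(blocks, inherits, TRUE, "ld_block")))
  values <- with_seed(seed, {
    cols <- lapply(blocks, function(b) {
      nh <- nrow(b$haplotypes)
      h1 <- sample.int(nh, n_individuals, replace = TRUE, prob = b$freq)
      h2 <- sample.int(nh, n_individuals, replace = TRUE, prob = b$freq)
      b$haplotypes[h1, , drop = FALSE] + b$haplotypes[h2, , drop = FALSE]
    })
    do.call(cbind, cols)
  })
  colnames(values) <- snp_ids %||% sprintf("S%05d", seq_len(ncol(values)))
  genotype_matrix(values,
                  snps = snp_layout(colnames(values), snps_per_chromosome,
                                    spacing_bp))
}

#' Covariate specification and simulator
#'
#' `default_covariate_spec()` emulates a typical exome-panel covariate set:
#' Age (uniform integer years), Sex and Smoke (binary), and Population
#' (7 categories). `simulate_covariates()` draws N rows from a spec.
#'
#' @return named list of per-covariate distributions; each element is a
#'   list with a `type` of `"uniform_int"` (`min`, `max`), `"binary"`
#'   (`p`), or `"categorical"` (`probs`, named, summing to 1).
#' @export
default_covariate_spec <- function() {
  list(
    Age = list(type = "uniform_int", min = 18L, max = 80L),
    Sex = list(type = "binary", p = 0.5),
    Smoke = list(type = "binary", p = 0.25),
    Population = list(type = "categorical",
                      probs = stats::setNames(rep(1 / 7, 7),
                                              paste0("pop", 1:7)))
  )
}

#' @param n_individuals sample size.
#' @param spec covariate spec, see [default_covariate_spec()].
#' @param seed optional seed.
#' @return data frame of covariates; categorical entries are factors.
#' @rdname default_covariate_spec
#' @export
simulate_covariates <- function(n_individuals,
                                spec = default_covariate_spec(),
                                seed = NULL) {
  with_seed(seed, {
    cols <- lapply(spec, function(s) {
      switch(s$type,
        uniform_int = sample(seq.int(s$min, s$max), n_individuals,
                             replace = TRUE),
        binary = {
          stopifnot(s$p >= 0, s$p <= 1)
          stats::rbinom(n_individuals, 1L, s$p)
        },
        categorical = {
          if (abs(sum(s$probs) - 1) > 1e-8)
            abort_ap("categorical probabilities must sum to 1",
                     class = "assocpower_validation_error")
          factor(sample(names(s$probs), n_individuals, replace = TRUE,
                        prob = s$probs),
                 levels = names(s$probs))
        },
        abort_ap("unknown covariate type '%s'", s$type,
                 class = "assocpower_validation_error"))
    })
    as.data.frame(cols, stringsAsFactors = FALSE)
  })
}

#' Simulate replicate quantitative traits
#'
#' Draws `n_replicates` trait vectors under the additive model
#' `Y = mu + Z alpha + X beta + eps` with normal errors. The genotypes and
#' covariates are fixed; only the error term is redrawn per replicate.
#' Missing genotypes are mean-imputed per SNP for the genetic component.
#'
#' @param g a [genotype_matrix()].
#' @param covariates covariate data frame (or `NULL` for none).
#' @param model a [trait_model()].
#' @param n_replicates number of replicate trait vectors.
#' @param seed optional seed.
#' @return numeric matrix, individuals x replicates, columns `rep_1`, ...
#' @export
simulate_traits <- function(g, covariates = NULL, model, n_replicates = 1L,
                            seed = NULL) {
  stopifnot(inherits(model, "trait_model"), n_replicates >= 1)
  n <- n_individuals(g)
  fixed <- rep(model$mu, n)
  if (!is.null(covariates) && length(model$covariate_effects) > 0) {
    zmat <- covariate_design(covariates, n, check_rank = FALSE)[, -1L,
                                                                drop = FALSE]
    a <- model$covariate_effects
    if (!is.null(names(a))) {
      miss <- setdiff(names(a), colnames(zmat))
      if (length(miss) > 0)
        abort_ap("covariate effect(s) for unknown column(s): %s",
                 paste(miss, collapse = ", "),
                 class = "assocpower_validation_error")
      a <- a[colnames(zmat)]
      a[is.na(a)] <- 0
    } else if (length(a) != ncol(zmat)) {
      abort_ap("covariate_effects has length %d but design has %d columns",
               length(a), ncol(zmat),
               class = "assocpower_validation_error")
    }
    fixed <- fixed + drop(zmat %*% a)
  }
  causal <- model_causal(model, g)
  if (length(causal$ids) > 0) {
    x <- impute_genotypes(g$values[, snp_index(g, causal$ids), drop = FALSE])
    fixed <- fixed + drop(x %*% causal$beta)
  }
  eps <- with_seed(seed, matrix(stats::rnorm(n * n_replicates,
                                             sd = model$error_sd),
                                n, n_replicates))
  y <- fixed + eps
  colnames(y) <- sprintf("rep_%d", seq_len(n_replicates))
  rownames(y) <- g$individual_ids
  y
}
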