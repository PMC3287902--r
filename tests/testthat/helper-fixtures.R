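# Fixtures are built in code at test time; nothing binary is stored.

# Small panel with two causal SNPs and a matching trait model.
make_causal_panel <- function(n = 300L, m = 40L, seed = 11L,
                              causal = c(5L, 20L), beta = c(0.3, 0.25),
                              error_sd = 1) {
  g <- simulate_genotypes_independent(
    with_fixed_seed(seed, stats::runif(m, 0.1, 0.5)), n, seed = seed + 1L)
  betas <- stats::setNames(beta, g$snps$snp_id[causal])
  g$snps$beta[causal] <- beta
  g$snps$is_causal[causal] <- TRUE
  list(g = g,
       model = trait_model(mu = 1, snp_effects = betas, error_sd = error_sd))
}

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Minimal VCF covering: normal site, ALT-major flip site, tie site,
# multi-allelic (skipped), missing GT.
write_test_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ind1", "ind2", "ind3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),                 # ALT freq 3/6 tie
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "1/1", "0/1", sep = "\t"),                 # ALT major -> flip
    paste("1", "300", "rs3", "G", "A,C", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1/2", sep = "\t"),                 # multi-allelic
    paste("2", "400", "rs4", "T", "C", ".", "PASS", ".", "GT",
          "./.", "0/1", "0/0", sep = "\t")                  # missing GT
  )
  writeLines(lines, path)
  path
}

# Two-SNP LD block from explicit haplotype frequencies p(00), p(01),
# p(10), p(11); returns the block plus the theoretical haplotype r.
two_snp_block <- function(p00, p01, p10, p11) {
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  freq <- c(p00, p01, p10, p11)
  p1 <- p10 + p11
  p2 <- p01 + p11
  d <- p11 - p1 * p2
  list(block = ld_block(haps, freq),
       r_theory = d / sqrt(p1 * (1 - p1) * p2 * (1 - p2)))
}
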