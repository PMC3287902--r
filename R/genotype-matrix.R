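#' Genotype matrix container
#'
#' Bundles an N individuals x M SNPs matrix of minor-allele counts (0/1/2,
#' `NA` for missing) with per-SNP metadata. This is the central container:
#' simulators produce it, readers construct it from VCF/TSV, and the score
#' test, power and correlation machinery consume it.
#'
#' @param values integer matrix, N individuals x M SNPs, entries 0/1/2 or
#'   `NA`. Column names, if present, are used as SNP ids.
#' @param snps optional data frame of SNP metadata with columns `snp_id`,
#'   `chromosome`, `position_bp` (1-based), and optionally `beta` (allele
#'   effect size, trait units per minor-allele copy; 0 for non-causal) and
#'   `is_causal`. When omitted, SNPs are laid out on synthetic chromosomes
#'   via [snp_layout()].
#' @param individual_ids optional character vector of N individual ids.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `snps` (metadata incl. an empirical `maf` column) and
#'   `individual_ids`.
#' @seealso [read_genotypes_tsv()], [read_genotypes_vcf()],
#'   [simulate_genotypes_independent()]
#' @export
genotype_matrix <- function(values, snps = NULL, individual_ids = NULL) {
  values <- as.matrix(values)
  if (length(values) == 0L || ncol(values) == 0L || nrow(values) == 0L)
    abort_ap("empty genotype matrix", class = "assocpower_empty_input")
  bad <- !is.na(values) & !(values %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    abort_ap("genotype entry at row %d, column %d is %s; must be 0, 1, 2 or NA",
             idx[1L], idx[2L], format(values[idx[1L], idx[2L]]),
             class = "assocpower_parse_error")
  }
  storage.mode(values) <- "integer"
  m <- ncol(values)
  ids <- colnames(values) %||% sprintf("S%05d", seq_len(m))
  if (is.null(snps)) {
    snps <- snp_layout(ids)
  } else {
    snps <- as.data.frame(snps, stringsAsFactors = FALSE)
    stopifnot(all(c("snp_id", "chromosome", "position_bp") %in% names(snps)))
    if (nrow(snps) != m)
      abort_ap("snps metadata has %d rows but matrix has %d columns",
               nrow(snps), m, class = "assocpower_validation_error")
    ids <- as.character(snps$snp_id)
  }
  if (is.null(snps$beta)) snps$beta <- 0
  if (is.null(snps$is_causal)) snps$is_causal <- snps$beta != 0
  if (any(snps$beta != 0 & !snps$is_causal))
    abort_ap("SNPs with nonzero beta must be flagged causal",
             class = "assocpower_validation_error")
  snps$maf <- apply(values, 2L, function(x)
    if (all(is.na(x))) NA_real_ else compute_maf(x))
  colnames(values) <- ids
  rownames(snps) <- NULL
  individual_ids <- individual_ids %||% rownames(values) %||%
    sprintf("I%05d", seq_len(nrow(values)))
  rownames(values) <- individual_ids
  structure(
    list(values = values, snps = snps, individual_ids = individual_ids),
    class = "genotype_matrix"
  )
}

#' Synthetic SNP layout
#'
#' Assigns SNPs to synthetic chromosomes and base-pair positions:
#' `snps_per_chromosome` SNPs per chromosome, evenly spaced `spacing_bp`
#' apart starting at position 1. The default spacing (1 Mb, 1000 SNPs per
#' chromosome) makes long-range exclusion rules (e.g. the 10 Mb rule in
#' [correlation_scan()]) exercisable on simulated panels.
#'
#' @param snp_ids character vector of SNP ids.
#' @param snps_per_chromosome SNPs placed per synthetic chromosome.
#' @param spacing_bp distance in base pairs between adjacent SNPs.
#' @return data frame with columns `snp_id`, `chromosome`, `position_bp`.
#' @export
snp_layout <- function(snp_ids, snps_per_chromosome = 1000L,
                       spacing_bp = 1e6) {
  m <- length(snp_ids)
  i <- seq_len(m) - 1L
  data.frame(
    snp_id = as.character(snp_ids),
    chromosome = sprintf("chr%d", i %/% snps_per_chromosome + 1L),
    position_bp = as.numeric((i %% snps_per_chromosome) * spacing_bp + 1),
    stringsAsFactors = FALSE
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  causal SNPs: %d\n", sum(x$snps$is_causal)))
  cat(sprintf("  MAF range: [%.4f, %.4f]   missing: %.2f%%\n",
              min(x$snps$maf, na.rm = TRUE), max(x$snps$maf, na.rm = TRUE),
              100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  genotype_matrix(x$values[i, j, drop = FALSE],
                  snps = x$snps[j, setdiff(names(x$snps), "maf"),
                                drop = FALSE],
                  individual_ids = x$individual_ids[i])
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

n_individuals <- function(g) nrow(g$values)
n_snps <- function(g) ncol(g$values)

# Column index of a SNP id, with a clear error.
snp_index <- function(g, snp_id) {
  j <- match(snp_id, g$snps$snp_id)
  if (anyNA(j))
    abort_ap("unknown SNP id(s): %s",
             paste(snp_id[is.na(j)], collapse = ", "),
             class = "assocpower_validation_error")
  j
}

#' Minor allele frequency of a genotype column
#'
#' `min(c, 1 - c)` where `c` is the coded-allele frequency
#' (sum of non-missing counts) / (2 x number of non-missing entries).
#' Missing entries are excluded pairwise.
#'
#' @param x numeric vector of 0/1/2 genotype counts, `NA` for missing.
#' @return frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    abort_ap("all genotypes missing; MAF undefined",
             class = "assocpower_degenerate_input")
  c_freq <- sum(x) / (2 * length(x))
  min(c_freq, 1 - c_freq)
}
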