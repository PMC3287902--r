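# Readers and writers for the plain-text exchange formats:
#   genotype TSV  — header = SNP ids, one row per individual, entries 0/1/2/NA
#   SNP metadata  — snp_id, chromosome, position_bp, beta
#   covariates    — header = names; character columns become factors
#   traits        — one column per replicate
# plus a VCF (v4.x, GT-only) genotype reader backed by vcfR.

#' Read genotypes from a VCF file
#'
#' Reads diallelic sites from a VCF and codes genotypes as minor-allele
#' counts. Sites whose ALT allele turns out to be the in-sample major
#' allele are flipped (`x -> 2 - x`) so that 2 always means two copies of
#' the minor allele; an exact in-sample frequency of 0.5 is resolved by
#' treating ALT as the minor allele. Multi-allelic sites are skipped with
#' a warning. Missing GT fields become `NA`.
#'
#' @param path path to a VCF (plain text or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path))
    abort_ap("cannot read VCF: %s", path, class = "assocpower_io_error")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  diallelic <- !is.na(alt) & !grepl(",", alt) & nchar(ref) >= 1
  if (sum(!diallelic) > 0)
    warning(sprintf("skipping %d multi-allelic or ALT-less site(s)",
                    sum(!diallelic)))
  if (sum(diallelic) == 0L)
    abort_ap("no diallelic sites in %s", path,
             class = "assocpower_empty_input")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[diallelic, , drop = FALSE]
  fix <- fix[diallelic, , drop = FALSE]
  counts <- apply(gt, c(1, 2), function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  })
  # orient each site to minor-allele counts; tie -> ALT treated as minor
  values <- t(apply(counts, 1L, function(x) {
    nm <- sum(!is.na(x))
    if (nm == 0L) return(x)
    if (sum(x, na.rm = TRUE) / (2 * nm) > 0.5) 2L - x else x
  }))
  if (ncol(gt) == 1L) values <- matrix(values, ncol = 1L)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  snps <- data.frame(snp_id = ids,
                     chromosome = fix[, "CHROM"],
                     position_bp = as.numeric(fix[, "POS"]),
                     stringsAsFactors = FALSE)
  gmat <- t(values)
  colnames(gmat) <- ids
  genotype_matrix(gmat, snps = snps, individual_ids = colnames(gt))
}

#' Read / write a genotype TSV
#'
#' The genotype TSV has a header row of SNP ids and one row per individual
#' (first column = individual id); entries are 0, 1, 2 or NA. The
#' round-trip `write_genotypes_tsv()` then `read_genotypes_tsv()` is
#' lossless for values and missingness.
#'
#' @param path file path.
#' @param snp_file optional SNP metadata TSV (see
#'   [read_snp_metadata_tsv()]); when given, chromosome/position/beta are
#'   attached by `snp_id`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(path, snp_file = NULL) {
  if (!file.exists(path))
    abort_ap("cannot read %s", path, class = "assocpower_io_error")
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#")
  if (nrow(raw) == 0L)
    abort_ap("no individuals in %s", path, class = "assocpower_empty_input")
  ind <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  if (ncol(body) == 0L)
    abort_ap("no SNP columns in %s", path, class = "assocpower_empty_input")
  ok <- c("0", "1", "2", "NA", "")
  for (j in seq_len(ncol(body))) {
    bad <- which(!(body[[j]] %in% ok | is.na(body[[j]])))
    if (length(bad) > 0)
      abort_ap("invalid genotype token '%s' at row %d, column '%s'",
               body[[j]][bad[1L]], bad[1L], names(body)[j],
               class = "assocpower_parse_error")
  }
  values <- vapply(body, function(col) {
    col[col == ""] <- NA_character_
    suppressWarnings(as.integer(col))
  }, integer(nrow(body)))
  if (nrow(body) == 1L)
    values <- matrix(values, nrow = 1L, dimnames = list(NULL, names(body)))
  snps <- if (!is.null(snp_file)) {
    meta <- read_snp_metadata_tsv(snp_file)
    meta[match(names(body), meta$snp_id), , drop = FALSE]
  }
  genotype_matrix(values, snps = snps, individual_ids = ind)
}

#' @param g a [genotype_matrix()].
#' @param header_lines optional character vector written as leading
#'   `#`-comment lines.
#' @rdname read_genotypes_tsv
#' @export
write_genotypes_tsv <- function(g, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  df <- data.frame(individual_id = g$individual_ids,
                   g$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write SNP metadata
#'
#' Columns: `snp_id`, `chromosome`, `position_bp` (1-based) and optionally
#' `beta` (allele effect size; nonzero marks a causal SNP).
#' @param path file path.
#' @export
read_snp_metadata_tsv <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("snp_id", "chromosome", "position_bp") %in% names(m)))
  m$snp_id <- as.character(m$snp_id)
  if (is.null(m$beta)) m$beta <- 0
  m
}

#' @param g a [genotype_matrix()].
#' @rdname read_snp_metadata_tsv
#' @export
write_snp_metadata_tsv <- function(g, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(
    g$snps[, c("snp_id", "chromosome", "position_bp", "beta")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a covariate TSV
#'
#' Header = covariate names, one row per individual. Character columns are
#' read as factors and are expanded to indicator columns (one level
#' dropped) wherever a design matrix is built.
#' @param path file path.
#' @return data frame of covariates.
#' @export
read_covariates_tsv <- function(path) {
  z <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = TRUE, comment.char = "#")
  if (nrow(z) == 0L)
    abort_ap("no rows in covariate file %s", path,
             class = "assocpower_empty_input")
  z
}

#' @param z covariate data frame.
#' @rdname read_covariates_tsv
#' @export
write_covariates_tsv <- function(z, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(z, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write trait replicates
#'
#' One column per replicate trait vector, one row per individual.
#' @param path file path.
#' @return numeric matrix, individuals x replicates.
#' @export
read_traits_tsv <- function(path) {
  y <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#")
  y <- as.matrix(y)
  if (!all(is.finite(y)))
    abort_ap("trait file %s contains non-finite values", path,
             class = "assocpower_validation_error")
  y
}

#' @param y trait matrix (individuals x replicates) or vector.
#' @rdname read_traits_tsv
#' @export
write_traits_tsv <- function(y, path, header_lines = NULL) {
  y <- as.matrix(y)
  if (is.null(colnames(y))) colnames(y) <- sprintf("rep_%d", seq_len(ncol(y)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(y, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
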