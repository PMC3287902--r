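# Hyper-LD diagnostics: genome-scale adjusted-correlation scans with a
# long-range distance exclusion, per-SNP counting of correlated partners,
# causal-partner histograms, and a MAF-matched linkage-equilibrium null
# comparison. Together these quantify how much apparent association signal
# at a test SNP can come from many weak — possibly purely chance —
# correlations with distant causal SNPs.

# Residualize and unit-normalize a block of genotype columns. Returns the
# normalized matrix plus a keep mask for degenerate columns.
normalized_block <- function(g, idx, qz) {
  x <- impute_genotypes(g$values[, idx, drop = FALSE])
  r <- qr.resid(qz, x)
  nrm <- sqrt(colSums(r^2))
  keep <- nrm > 1e-10 * pmax(1, sqrt(colSums(x^2)))
  r[, keep] <- sweep(r[, keep, drop = FALSE], 2L, nrm[keep], "/")
  list(r = r, keep = keep)
}

#' Adjusted-correlation scan with distance exclusion
#'
#' Emits every (target, partner) pair whose covariate-adjusted genotype
#' correlation exceeds `threshold` (signed `r > threshold` by default;
#' `signed = FALSE` uses `|r| > threshold`), excluding self-pairs and
#' same-chromosome pairs closer than `min_distance_bp` (default 10 Mb —
#' pairs on different chromosomes are never excluded). The scan runs
#' blockwise over column blocks so peak memory is governed by
#' `block_size`, not by the number of emitted pairs times panel size.
#'
#' @param g a [genotype_matrix()].
#' @param covariates covariate data frame or `NULL` (raw correlations).
#' @param targets,partners optional SNP id subsets; default the full
#'   panel for both. Pairs are ordered: each target is paired with every
#'   eligible partner, so with both subsets equal to the panel the output
#'   is symmetric.
#' @param threshold correlation threshold, > 0.
#' @param min_distance_bp minimum same-chromosome distance in bp.
#' @param signed if `TRUE` (default) emit `r > threshold`; if `FALSE`
#'   emit `|r| > threshold`.
#' @param block_size columns per block of the streaming kernel; results
#'   are independent of it.
#' @return data frame with columns `target`, `partner`, `r`.
#' @export
correlation_scan <- function(g, covariates = NULL, targets = NULL,
                             partners = NULL, threshold = 0.1,
                             min_distance_bp = 1e7, signed = TRUE,
                             block_size = 512L) {
  stopifnot(threshold > 0, min_distance_bp >= 0, block_size >= 1)
  ti <- if (is.null(targets)) seq_len(n_snps(g)) else snp_index(g, targets)
  pi <- if (is.null(partners)) seq_len(n_snps(g)) else snp_index(g, partners)
  qz <- design_qr(covariates, n_individuals(g))
  chrom <- g$snps$chromosome
  pos <- g$snps$position_bp
  ids <- g$snps$snp_id
  t_blocks <- split(ti, ceiling(seq_along(ti) / block_size))
  p_blocks <- split(pi, ceiling(seq_along(pi) / block_size))
  n_degenerate <- 0L
  out <- list()
  for (tb in t_blocks) {
    nt <- normalized_block(g, tb, qz)
    n_degenerate <- n_degenerate + sum(!nt$keep)
    tb_keep <- tb[nt$keep]
    if (length(tb_keep) == 0L) next
    rt <- nt$r[, nt$keep, drop = FALSE]
    for (pb in p_blocks) {
      np <- normalized_block(g, pb, qz)
      pb_keep <- pb[np$keep]
      if (length(pb_keep) == 0L) next
      rmat <- crossprod(rt, np$r[, np$keep, drop = FALSE])
      hit <- if (signed) rmat > threshold else abs(rmat) > threshold
      # self-pairs and same-chromosome near pairs are excluded
      same <- outer(tb_keep, pb_keep, "==")
      near <- outer(chrom[tb_keep], chrom[pb_keep], "==") &
        abs(outer(pos[tb_keep], pos[pb_keep], "-")) < min_distance_bp
      hit <- hit & !same & !near
      if (any(hit)) {
        w <- which(hit, arr.ind = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          target = ids[tb_keep][w[, 1L]],
          partner = ids[pb_keep][w[, 2L]],
          r = rmat[w],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_degenerate > 0)
    message(sprintf("correlation_scan: skipped %d degenerate column pass(es)",
                    n_degenerate))
  if (length(out) == 0L)
    return(data.frame(target = character(0), partner = character(0),
                      r = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count correlated partners per target SNP
#'
#' Summarizes a [correlation_scan()] result into one row per target SNP:
#' the number of emitted partners, the number that are causal, the
#' target's MAF (for MAF-vs-count reporting), and — when a
#' [trait_model()] is supplied — the cumulative effect `sum(r * h)` over
#' the causal partners that appear in the scan.
#'
#' @param pairs data frame from [correlation_scan()].
#' @param g the scanned [genotype_matrix()].
#' @param targets optional SNP ids to report (default: all panel SNPs);
#'   targets with no emitted pair get zero counts.
#' @param model optional [trait_model()] supplying `h_j` for the
#'   cumulative-effect column.
#' @param covariates covariates used in the scan (for `h_j`).
#' @return data frame: `snp_id`, `maf`, `n_correlated`,
#'   `n_correlated_causal`, `cumulative_effect`.
#' @export
count_correlated <- function(pairs, g, targets = NULL, model = NULL,
                             covariates = NULL) {
  ids <- if (is.null(targets)) g$snps$snp_id else as.character(targets)
  causal_ids <- g$snps$snp_id[g$snps$is_causal]
  n_cor <- table(factor(pairs$target, levels = ids))
  causal_pairs <- pairs[pairs$partner %in% causal_ids, , drop = FALSE]
  n_cau <- table(factor(causal_pairs$target, levels = ids))
  cum <- rep(NA_real_, length(ids))
  if (!is.null(model) && nrow(causal_pairs) > 0) {
    s_yy <- model_residual_variance(model, g, covariates)
    h <- vapply(causal_ids, function(id)
      direct_effect(model$snp_effects[[id]] %||% 0,
                    g$values[, snp_index(g, id)], covariates, s_yy),
      numeric(1))
    names(h) <- causal_ids
    cum <- vapply(ids, function(t) {
      cp <- causal_pairs[causal_pairs$target == t, , drop = FALSE]
      if (nrow(cp) == 0L) 0 else sum(cp$r * h[cp$partner])
    }, numeric(1))
  } else if (!is.null(model)) {
    cum <- rep(0, length(ids))
  }
  data.frame(
    snp_id = ids,
    maf = g$snps$maf[match(ids, g$snps$snp_id)],
    n_correlated = as.integer(n_cor),
    n_correlated_causal = as.integer(n_cau),
    cumulative_effect = unname(cum),
    stringsAsFactors = FALSE
  )
}

#' Histogram of causal-partner counts
#'
#' Bins the per-SNP counts of correlated causal partners into the bins
#' 0, 1, ..., 7, >7. Bin totals always sum to the number of target SNPs.
#'
#' @param rows data frame from [count_correlated()].
#' @return data frame with `bin` (factor) and `n_snps`.
#' @export
causal_count_histogram <- function(rows) {
  bins <- c(as.character(0:7), ">7")
  b <- ifelse(rows$n_correlated_causal > 7, ">7",
              as.character(rows$n_correlated_causal))
  tab <- table(factor(b, levels = bins))
  data.frame(bin = factor(bins, levels = bins),
             n_snps = as.integer(tab))
}

#' Observed vs matched linkage-equilibrium null comparison
#'
#' Re-simulates the panel as independent HWE SNPs with the same MAFs
#' (and the same causal flags and chromosome layout), runs the identical
#' scan / count / histogram pipeline on both, and returns the two
#' summaries side by side. On a panel with genuine LD the observed counts
#' stochastically exceed the null counts; on an already-independent panel
#' the two agree in distribution.
#'
#' @inheritParams correlation_scan
#' @param seed seed for the null panel (deterministic given seed).
#' @return list with `observed` / `null` (count data frames) and
#'   `observed_histogram` / `null_histogram`.
#' @export
null_panel_comparison <- function(g, covariates = NULL, threshold = 0.1,
                                  min_distance_bp = 1e7, signed = TRUE,
                                  seed = NULL, block_size = 512L) {
  run <- function(panel) {
    pairs <- correlation_scan(panel, covariates, threshold = threshold,
                              min_distance_bp = min_distance_bp,
                              signed = signed, block_size = block_size)
    count_correlated(pairs, panel)
  }
  g_null <- simulate_genotypes_independent(
    g$snps$maf, n_individuals(g), seed = seed, snp_ids = g$snps$snp_id)
  # carry over layout and causal flags so the comparison is like for like
  g_null$snps$chromosome <- g$snps$chromosome
  g_null$snps$position_bp <- g$snps$position_bp
  g_null$snps$is_causal <- g$snps$is_causal
  g_null$snps$beta <- g$snps$beta
  obs <- run(g)
  nul <- run(g_null)
  list(observed = obs, null = nul,
       observed_histogram = causal_count_histogram(obs),
       null_histogram = causal_count_histogram(nul))
}

#' Cumulative-effect breakdown at a test SNP
#'
#' The diagnosis for a test SNP whose power is suspected to come from the
#' hyper-LD effect: lists the causal SNPs with adjusted correlation above
#' `r_threshold` (their `r`, `h` and products), reports the cumulative
#' effect `sum(r * h)` over ALL causal SNPs (no distance exclusion — the
#' point is precisely that distant SNPs contribute), and ranks that
#' cumulative effect against every causal SNP's own direct effect `h_j`.
#'
#' @inheritParams noncentrality
#' @param r_threshold correlation level for the listed table.
#' @return list with `test_snp`, `correlated_causal` (data frame),
#'   `cumulative_effect`, `lambda`, `n_direct_effects_exceeded` (number
#'   of causal SNPs whose `|h_j|` is below the |cumulative effect|) and
#'   `n_causal`.
#' @export
cumulative_effect_report <- function(g, covariates = NULL, model, test_snp,
                                     r_threshold = 0.1) {
  ncp <- noncentrality(g, covariates, model, test_snp)
  per <- ncp$per_causal
  listed <- per[per$r > r_threshold, , drop = FALSE]
  list(
    test_snp = test_snp,
    correlated_causal = listed,
    cumulative_effect = ncp$cumulative,
    lambda = ncp$lambda,
    n_direct_effects_exceeded = sum(abs(per$h) < abs(ncp$cumulative)),
    n_causal = nrow(per)
  )
}
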