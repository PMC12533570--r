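#' STR dosage - expression association scan
#'
#' For every (hypervariable locus, gene) pair whose locus start lies within
#' `window_bp` of the gene's TSS, fits ordinary least squares of the
#' expression value on the z-score-normalized dosage plus covariates, over
#' pairwise-complete samples: `Y = X beta + W alpha + eps`. Reports the
#' dosage coefficient's estimate, standard error and two-sided p-value.
#'
#' @param d DosageMatrix (samples x loci, locus table attached).
#' @param expr samples x genes expression matrix (typically already
#'   rank-inverse-normalized; see [rank_inverse_normal()]).
#' @param covariates samples x covariates numeric matrix (no intercept).
#' @param genes annotation data.frame: `gene_id`, `chrom`, `tss`.
#' @param window_bp cis window around the TSS (default 500000).
#' @param het_floor hypervariability gate on expected heterozygosity.
#' @param min_n minimum complete samples per pair (default 30); pairs below
#'   it are skipped and counted.
#' @param summaries optional precomputed [summarize_loci()]-style data.frame
#'   with `locus_id` and `heterozygosity`; computed from dosages if absent.
#' @return data.frame of class `eqtl_records`: locus_id, gene_id, beta, se,
#'   p_raw, distance_to_tss; attribute `n_skipped` counts skipped pairs.
#' @export
eqtl_scan <- function(d, expr, covariates, genes, window_bp = 500000,
                      het_floor = 0.1, min_n = 30, summaries = NULL) {
  loci <- attr(d, "loci")
  stopifnot(!is.null(loci), all(c("gene_id", "chrom", "tss") %in% names(genes)))
  samples <- rownames(d)
  if (is.null(samples) || is.null(rownames(expr))) {
    stop("dosage and expression matrices must carry sample rownames")
  }
  common <- intersect(samples, rownames(expr))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    common <- intersect(common, rownames(covariates))
    W <- covariates[common, , drop = FALSE]
  } else {
    W <- NULL
  }
  d <- d[common, , drop = FALSE]
  expr <- expr[common, , drop = FALSE]

  het <- if (!is.null(summaries)) {
    stats::setNames(summaries$heterozygosity, summaries$locus_id)[loci$locus_id]
  } else {
    apply(d, 2, dosage_heterozygosity)
  }
  hyper <- !is.na(het) & het > het_floor

  out <- list()
  n_skipped <- 0L
  for (gi in seq_len(nrow(genes))) {
    gene <- genes$gene_id[gi]
    if (!gene %in% colnames(expr)) next
    in_win <- which(hyper & loci$chrom == genes$chrom[gi] &
                      abs(loci$pos_start - genes$tss[gi]) <= window_bp)
    if (!length(in_win)) next
    y_all <- expr[, gene]
    for (li in in_win) {
      x_all <- d[, li]
      ok <- !is.na(x_all) & !is.na(y_all)
      if (!is.null(W)) ok <- ok & stats::complete.cases(W)
      if (sum(ok) < min_n) { n_skipped <- n_skipped + 1L; next }
      z <- zscore(x_all[ok])
      if (isTRUE(attr(z, "zero_variance"))) { n_skipped <- n_skipped + 1L; next }
      X <- if (is.null(W)) cbind(dosage = z) else cbind(dosage = z, W[ok, , drop = FALSE])
      co <- ols_coef(y_all[ok], X, coef_idx = 1L)
      out[[length(out) + 1L]] <- data.frame(
        locus_id = loci$locus_id[li], gene_id = gene,
        beta = co[["beta"]], se = co[["se"]], p_raw = co[["p"]],
        distance_to_tss = loci$pos_start[li] - genes$tss[gi],
        n = sum(ok), stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(0), gene_id = character(0),
               beta = numeric(0), se = numeric(0), p_raw = numeric(0),
               distance_to_tss = numeric(0), n = integer(0))
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("eqtl_records", class(res))
  res
}

# expected heterozygosity of the allele spectrum implied by a dosage vector is
# not recoverable from dosages alone; this helper gates on dosage variability
# instead (dosage-level expected het), used only when locus summaries are not
# supplied.
dosage_heterozygosity <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  p <- table(x) / length(x)
  1 - sum(p^2)
}

#' Call eQTLs and eSTR genes from scan records
#'
#' Two-stage multiplicity control: per gene, raw p-values are Bonferroni
#' adjusted for the number of pairs actually fitted for that gene
#' (`p_bonf = min(1, p * m_gene)`); pairs with `p_bonf < alpha` are eQTLs.
#' Genes with at least one eQTL contribute their smallest adjusted p, which
#' is Benjamini-Hochberg corrected across genes; genes with q below the FDR
#' cut are eSTR genes, reported with their top locus.
#'
#' @param records [eqtl_scan()] output.
#' @param alpha pair-level significance on the Bonferroni scale (default 0.05).
#' @param fdr gene-level FDR (default 0.05).
#' @return list: `records` (with `p_bonf_gene` added), `eqtls` (significant
#'   pairs), `genes` (gene_id, min_p_bonf, q, top locus, is_estr), `estr`
#'   (character vector of eSTR gene ids).
#' @export
call_eqtl_estr <- function(records, alpha = 0.05, fdr = 0.05) {
  stopifnot(all(c("locus_id", "gene_id", "p_raw") %in% names(records)))
  rec <- as.data.frame(records)
  if (!nrow(rec)) {
    return(list(records = rec, eqtls = rec,
                genes = data.frame(gene_id = character(0), min_p_bonf = numeric(0),
                                   q = numeric(0), top_locus = character(0),
                                   is_estr = logical(0)),
                estr = character(0)))
  }
  m_gene <- table(rec$gene_id)
  rec$p_bonf_gene <- pmin(1, rec$p_raw * as.numeric(m_gene[rec$gene_id]))
  eqtls <- rec[rec$p_bonf_gene < alpha, , drop = FALSE]
  if (nrow(eqtls)) {
    ord <- order(eqtls$gene_id, eqtls$p_bonf_gene, eqtls$locus_id)
    e <- eqtls[ord, ]
    first <- !duplicated(e$gene_id)
    genes <- data.frame(gene_id = e$gene_id[first],
                        min_p_bonf = e$p_bonf_gene[first],
                        top_locus = e$locus_id[first],
                        stringsAsFactors = FALSE)
    genes$q <- stats::p.adjust(genes$min_p_bonf, method = "BH")
    genes$is_estr <- genes$q < fdr
  } else {
    genes <- data.frame(gene_id = character(0), min_p_bonf = numeric(0),
                        top_locus = character(0), q = numeric(0),
                        is_estr = logical(0))
  }
  list(records = rec, eqtls = eqtls, genes = genes,
       estr = genes$gene_id[genes$is_estr])
}

#' Permuted-identifier negative control for the eQTL scan
#'
#' Permutes the sample identifiers of the expression matrix relative to the
#' genotypes (the covariates travel with expression, so only the
#' genotype-phenotype link is broken) and reruns the scan; the resulting
#' p-value set is the empirical null for QQ diagnostics.
#'
#' @param d,expr,covariates,genes,... as in [eqtl_scan()].
#' @param seed RNG seed; the same seed reproduces the same permutation.
#' @param identity if TRUE, use the identity permutation (reproduces
#'   [eqtl_scan()] exactly).
#' @return the permuted-scan records, with the permutation as attribute
#'   `"perm"`.
#' @export
permutation_control <- function(d, expr, covariates, genes, seed = 1,
                                identity = FALSE, ...) {
  samples <- intersect(rownames(d), rownames(expr))
  perm <- if (identity) seq_along(samples) else
    with_seed(seed, sample(length(samples)))
  expr2 <- expr[samples[perm], , drop = FALSE]
  rownames(expr2) <- samples
  cov2 <- covariates
  if (!is.null(covariates)) {
    cov2 <- as.matrix(covariates)[samples[perm], , drop = FALSE]
    rownames(cov2) <- samples
  }
  res <- eqtl_scan(d, expr2, cov2, genes, ...)
  attr(res, "perm") <- perm
  res
}

#' Resampling enrichment of a hit set within a locus category
#'
#' Per replicate, samples `ceil(frac * size)` loci from the category and the
#' same fraction from its complement within the universe, and records the
#' proportion of each draw that falls in the hit set. The two 2000-length
#' proportion vectors are compared with a two-sided Wilcoxon rank-sum test
#' (the pseudo-replicates are not independent draws; the test is reproduced
#' as the field reports it).
#'
#' @param category locus ids forming the category of interest.
#' @param universe all candidate locus ids (category plus complement).
#' @param hit_set locus ids counted as hits (e.g. eQTL loci).
#' @param frac sampling fraction (default 0.10).
#' @param reps replicates (default 2000).
#' @param seed RNG seed.
#' @return list: `prop_category`, `prop_complement` (length-`reps` vectors),
#'   `diff` (mean difference), `p` (Wilcoxon two-sided).
#' @export
category_enrichment <- function(category, universe, hit_set, frac = 0.10,
                                reps = 2000, seed = 1) {
  category <- intersect(category, universe)
  complement <- setdiff(universe, category)
  if (!length(category) || !length(complement)) {
    stop("category and its complement must both be non-empty within the universe")
  }
  n_cat <- max(1L, ceiling(frac * length(category)))
  n_comp <- max(1L, ceiling(frac * length(complement)))
  hit <- stats::setNames(universe %in% hit_set, universe)
  with_seed(seed, {
    pc <- numeric(reps); px <- numeric(reps)
    for (r in seq_len(reps)) {
      pc[r] <- mean(hit[sample(category, n_cat)])
      px[r] <- mean(hit[sample(complement, n_comp)])
    }
    p <- tryCatch(
      stats::wilcox.test(pc, px, alternative = "two.sided", exact = FALSE)$p.value,
      error = function(e) NA_real_
    )
    list(prop_category = pc, prop_complement = px,
         diff = mean(pc) - mean(px), p = p)
  })
}
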