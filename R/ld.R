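#' SNP-STR linkage disequilibrium within a window
#'
#' For each population (subsampled to at most `max_n` individuals, seeded)
#' and each SNP, computes the squared Pearson correlation between the SNP
#' dosage (0/1/2) and the dosage of every STR locus on the same chromosome
#' whose start lies within `window_bp` of the SNP, over pairwise-complete
#' samples. Pairs with `r2 > 0.8` are flagged colocalized. Distance is
#' measured from the SNP position to the STR `pos_start`.
#'
#' @param snp_dosage samples x SNPs matrix (0/1/2, NAs allowed).
#' @param snp_pos data.frame: `snp_id`, `chrom`, `pos`.
#' @param d DosageMatrix.
#' @param pops named population vector; `NULL` treats the cohort as one
#'   population labelled `"ALL"`.
#' @param window_bp window (default 200000).
#' @param max_n per-population subsample cap (default 100).
#' @param seed RNG seed for subsampling.
#' @param min_n minimum complete pairs (default 10).
#' @return data.frame: snp_id, locus_id, population, distance_bp, r2, n_used,
#'   colocalized. Constant vectors yield skipped pairs, counted in attribute
#'   `"n_skipped"`.
#' @export
snp_str_ld <- function(snp_dosage, snp_pos, d, pops = NULL,
                       window_bp = 200000, max_n = 100, seed = 1, min_n = 10) {
  loci <- attr(d, "loci")
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snp_pos)))
  samples <- intersect(rownames(snp_dosage), rownames(d))
  if (is.null(pops)) pops <- stats::setNames(rep("ALL", length(samples)), samples)
  labs <- unique(pops[samples])
  out <- list()
  n_skipped <- 0L
  for (p in labs) {
    ids <- samples[pops[samples] == p]
    sub <- with_seed(derive_seed(seed, p), {
      if (length(ids) > max_n) ids[sort(sample.int(length(ids), max_n))] else ids
    })
    for (si in seq_len(nrow(snp_pos))) {
      in_win <- which(loci$chrom == snp_pos$chrom[si] &
                        abs(loci$pos_start - snp_pos$pos[si]) <= window_bp)
      if (!length(in_win)) next
      x <- snp_dosage[sub, snp_pos$snp_id[si]]
      for (li in in_win) {
        y <- d[sub, li]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < min_n) { n_skipped <- n_skipped + 1L; next }
        if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          n_skipped <- n_skipped + 1L; next
        }
        r2 <- stats::cor(x[ok], y[ok])^2
        out[[length(out) + 1L]] <- data.frame(
          snp_id = snp_pos$snp_id[si], locus_id = loci$locus_id[li],
          population = p,
          distance_bp = loci$pos_start[li] - snp_pos$pos[si],
          r2 = r2, n_used = sum(ok), colocalized = r2 > 0.8,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snp_id = character(0), locus_id = character(0),
               population = character(0), distance_bp = numeric(0),
               r2 = numeric(0), n_used = integer(0), colocalized = logical(0))
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Binned LD decay curve
#'
#' Bins LD records by absolute distance and reports the mean r2 and record
#' count per bin and population.
#'
#' @param records [snp_str_ld()] output.
#' @param bin_width_bp bin width (default 20000).
#' @return data.frame: population, bin_start, bin_mid, mean_r2, n.
#' @export
ld_decay <- function(records, bin_width_bp = 20000) {
  if (!nrow(records)) {
    return(data.frame(population = character(0), bin_start = numeric(0),
                      bin_mid = numeric(0), mean_r2 = numeric(0), n = integer(0)))
  }
  bin <- floor(abs(records$distance_bp) / bin_width_bp) * bin_width_bp
  agg <- stats::aggregate(records$r2,
                          by = list(population = records$population, bin_start = bin),
                          FUN = function(v) c(mean(v), length(v)))
  data.frame(population = agg$population, bin_start = agg$bin_start,
             bin_mid = agg$bin_start + bin_width_bp / 2,
             mean_r2 = agg$x[, 1], n = as.integer(agg$x[, 2]),
             stringsAsFactors = FALSE)
}

#' Resampling distribution of GWAS-tagging proportions per category
#'
#' Per replicate and category, samples `ceil(frac * |category|)` loci and
#' records the fraction belonging to the tagged set; a baseline category
#' drawn from the whole universe is always included.
#'
#' @param categories named list of locus-id vectors.
#' @param universe all locus ids.
#' @param tagged locus ids tagged (e.g. in strong LD with a risk SNP).
#' @param frac sampling fraction (default 0.10).
#' @param reps replicates (default 2000).
#' @param seed RNG seed.
#' @return list: `distributions` (reps x categories matrix, including
#'   `baseline`), `means` (named vector).
#' @export
tagging_enrichment <- function(categories, universe, tagged, frac = 0.10,
                               reps = 2000, seed = 1) {
  stopifnot(is.list(categories), length(universe) > 0)
  cats <- c(categories, list(baseline = universe))
  is_tagged <- stats::setNames(universe %in% tagged, universe)
  with_seed(seed, {
    dist <- matrix(NA_real_, reps, length(cats),
                   dimnames = list(NULL, names(cats)))
    for (ci in seq_along(cats)) {
      members <- intersect(cats[[ci]], universe)
      if (!length(members)) next
      k <- max(1L, ceiling(frac * length(members)))
      for (r in seq_len(reps)) {
        dist[r, ci] <- mean(is_tagged[sample(members, k)])
      }
    }
    list(distributions = dist, means = colMeans(dist, na.rm = TRUE))
  })
}
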