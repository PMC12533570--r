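#' Detect highly expanded or contracted alleles
#'
#' Within each population, an allele at a locus is an expansion/contraction
#' outlier when all three criteria hold: (i) motif length >= 3 bp;
#' (ii) |allele - major| >= 10 repeat units; (iii) |allele - major| >= 50%
#' of the major allele, where the major allele is computed within the
#' studied population (ties broken toward the shorter allele).
#'
#' @param g StrGenotypes.
#' @param pops named population vector.
#' @return data.frame: locus_id, population, direction
#'   (`"expanded"`/`"contracted"`), allele, major_allele, delta_vs_major,
#'   n_carriers, carrier sample ids (comma-joined).
#' @export
find_outlier_alleles <- function(g, pops) {
  stopifnot(inherits(g, "StrGenotypes"))
  labs <- unique(pops[g$samples])
  motif_ok <- nchar(g$loci$motif) >= 3
  out <- list()
  for (p in labs) {
    cols <- which(pops[g$samples] == p)
    for (l in which(motif_ok)) {
      al <- c(g$a1[l, cols], g$a2[l, cols])
      keep <- !is.na(al)
      if (!any(keep)) next
      al <- al[keep]
      tab <- table(al)
      units <- as.numeric(names(tab))
      major <- units[order(-as.numeric(tab), units)][1]
      delta <- units - major
      hit <- abs(delta) >= 10 & abs(delta) >= 0.5 * major
      for (u in units[hit]) {
        carrier_cols <- cols[!is.na(g$a1[l, cols]) &
                               (g$a1[l, cols] == u | g$a2[l, cols] == u)]
        out[[length(out) + 1L]] <- data.frame(
          locus_id = g$loci$locus_id[l], population = p,
          direction = if (u > major) "expanded" else "contracted",
          allele = u, major_allele = major, delta_vs_major = u - major,
          n_carriers = length(carrier_cols),
          carriers = paste(g$samples[carrier_cols], collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(locus_id = character(0), population = character(0),
                      direction = character(0), allele = numeric(0),
                      major_allele = numeric(0), delta_vs_major = numeric(0),
                      n_carriers = integer(0), carriers = character(0)))
  }
  do.call(rbind, out)
}

#' Expansion score of an allele-length vector
#'
#' `(95th percentile - median) / median` of the allele lengths within one
#' population; the percentile uses linear interpolation (R quantile type 7).
#' A constant vector scores 0.
#'
#' @param lengths numeric vector of allele lengths (repeat units); NAs dropped.
#' @return non-negative real (0 for empty input).
#' @export
expansion_score <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (!length(lengths)) return(NA_real_)
  med <- stats::median(lengths)
  if (med == 0) return(NA_real_)
  (stats::quantile(lengths, 0.95, names = FALSE, type = 7) - med) / med
}

#' Cross-population expansion profile
#'
#' Scores every locus in every population and keeps loci whose maximum
#' population score reaches `score_floor`; alongside, the coefficient of
#' variation (sd/mean of allele lengths) per retained locus and population
#' is emitted for external clustering.
#'
#' @param g StrGenotypes.
#' @param pops named population vector.
#' @param score_floor retention threshold on the max population score
#'   (default 2).
#' @return list: `scores` (retained loci x populations), `cv` (same shape),
#'   `all_scores` (every locus, before filtering).
#' @export
expansion_profile <- function(g, pops, score_floor = 2.0) {
  stopifnot(inherits(g, "StrGenotypes"))
  labs <- unique(pops[g$samples])
  n_loci <- nrow(g$loci)
  scores <- matrix(NA_real_, n_loci, length(labs),
                   dimnames = list(g$loci$locus_id, labs))
  cv <- scores
  for (p in labs) {
    cols <- which(pops[g$samples] == p)
    for (l in seq_len(n_loci)) {
      al <- c(g$a1[l, cols], g$a2[l, cols])
      al <- al[!is.na(al)]
      if (!length(al)) next
      scores[l, p] <- expansion_score(al)
      m <- mean(al)
      cv[l, p] <- if (m > 0) stats::sd(al) / m else NA_real_
    }
  }
  mx <- apply(scores, 1, function(r) if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
  keep <- mx >= score_floor
  list(scores = scores[keep, , drop = FALSE], cv = cv[keep, , drop = FALSE],
       all_scores = scores)
}

#' Between-group allele-length outlier test
#'
#' Per locus, compares allele lengths between two groups with a two-sided
#' Wilcoxon rank-sum test, reports the fold change of mean lengths
#' (group A / group B), and Benjamini-Hochberg adjusts across loci; outliers
#' have adjusted p < 0.05.
#'
#' @param g StrGenotypes.
#' @param pops named population vector.
#' @param group_a,group_b population labels (vectors pool several labels).
#' @param loci optional locus-id subset.
#' @return data.frame: locus_id, mean_a, mean_b, fold_change, p, q, outlier.
#' @export
length_difference_test <- function(g, pops, group_a, group_b, loci = NULL) {
  stopifnot(inherits(g, "StrGenotypes"))
  ids <- if (is.null(loci)) g$loci$locus_id else loci
  cols_a <- which(pops[g$samples] %in% group_a)
  cols_b <- which(pops[g$samples] %in% group_b)
  if (!length(cols_a) || !length(cols_b)) stop("empty group")
  out <- list()
  for (id in ids) {
    l <- match(id, g$loci$locus_id)
    if (is.na(l)) stop("unknown locus: ", id)
    la <- c(g$a1[l, cols_a], g$a2[l, cols_a]); la <- la[!is.na(la)]
    lb <- c(g$a1[l, cols_b], g$a2[l, cols_b]); lb <- lb[!is.na(lb)]
    if (length(la) < 2 || length(lb) < 2) next
    p <- tryCatch(
      stats::wilcox.test(la, lb, alternative = "two.sided", exact = FALSE)$p.value,
      error = function(e) NA_real_
    )
    if (is.nan(p)) p <- 1  # all values tied across both groups
    out[[length(out) + 1L]] <- data.frame(
      locus_id = id, mean_a = mean(la), mean_b = mean(lb),
      fold_change = mean(la) / mean(lb), p = p, stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(0), mean_a = numeric(0), mean_b = numeric(0),
               fold_change = numeric(0), p = numeric(0))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$outlier <- !is.na(res$q) & res$q < 0.05
  res
}

#' TRDS of each population against a random-control null at a pathogenic locus
#'
#' The observed statistic per population is the TRDS between that
#' population's allele distribution and the allele distribution of
#' `n_control` randomly sampled cohort individuals. The null distribution is
#' built by repeatedly redrawing both sides at random from the cohort: per
#' replicate, a pseudo-population of the same size and a fresh control set
#' are drawn and their TRDS recorded. A population is flagged when its
#' observed TRDS exceeds the null's 95th percentile. Alleles exceeding the
#' pathogenic threshold are counted per population.
#'
#' @param g StrGenotypes.
#' @param pops named population vector.
#' @param locus_id locus to test.
#' @param pathogenic_threshold repeat units above which an allele is in the
#'   pathogenic range.
#' @param n_control control sample size (default 500; capped at the cohort).
#' @param reps null replicates (default 200).
#' @param seed RNG seed.
#' @return data.frame: population, n, trds_observed, null_q95, flagged,
#'   n_pathogenic_alleles.
#' @export
pathogenic_trds_null <- function(g, pops, locus_id, pathogenic_threshold,
                                 n_control = 500, reps = 200, seed = 1) {
  stopifnot(inherits(g, "StrGenotypes"), pathogenic_threshold > 0)
  labs <- unique(pops[g$samples])
  n_control <- min(n_control, length(g$samples))
  with_seed(seed, {
    control_ids <- sample(g$samples, n_control)
    f_control <- allele_distribution(g, locus_id, control_ids)
    out <- list()
    for (p in labs) {
      ids <- g$samples[pops[g$samples] == p]
      fp <- allele_distribution(g, locus_id, ids)
      if (!length(fp) || !length(f_control)) next
      obs <- trds(fp, f_control)
      null <- vapply(seq_len(reps), function(r) {
        pseudo <- sample(g$samples, length(ids))
        ctrl <- sample(g$samples, n_control)
        trds(allele_distribution(g, locus_id, pseudo),
             allele_distribution(g, locus_id, ctrl))
      }, 0)
      q95 <- stats::quantile(null, 0.95, names = FALSE, type = 7)
      al <- c(g$a1[match(locus_id, g$loci$locus_id), match(ids, g$samples)],
              g$a2[match(locus_id, g$loci$locus_id), match(ids, g$samples)])
      out[[length(out) + 1L]] <- data.frame(
        population = p, n = length(ids), trds_observed = obs, null_q95 = q95,
        flagged = obs > q95,
        n_pathogenic_alleles = sum(al > pathogenic_threshold, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Read a pathogenic-locus catalog
#'
#' @param path TSV with columns `locus_id`, `gene`, `motif`,
#'   `pathogenic_threshold_units` and optionally `inheritance`.
#' @return data.frame.
#' @export
read_pathogenic_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("locus_id", "gene", "pathogenic_threshold_units") %in% names(df)))
  if (any(df$pathogenic_threshold_units <= 0)) stop("pathogenic threshold must be > 0")
  df
}
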