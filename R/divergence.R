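#' Rst: dosage-variance fixation index for one locus and population pair
#'
#' Decomposes the total dosage variance of the pooled (subsampled) groups
#' into within- and between-population components:
#' `S_bar` is the total variance of the pooled dosages (denominator N),
#' `Sw` the sample-size-weighted mean of within-population variances
#' (denominator n_k), and `Rst = (S_bar - Sw) / S_bar`. With these plug-in
#' variances Rst is exactly 0 when the two groups have identical dosage
#' lists and exactly 1 when each group is fixed for a different dosage.
#' Each population is first subsampled without replacement to at most
#' `max_n` called individuals (seeded), mirroring the balanced-sample
#' convention for cross-population comparisons.
#'
#' @param d DosageMatrix.
#' @param pops named population vector.
#' @param locus_id locus to test.
#' @param pop_a,pop_b population labels.
#' @param max_n subsample cap per population (default 100).
#' @param seed RNG seed for the subsampling.
#' @return list: `rst` (NA with `undefined = TRUE` when the pooled variance
#'   is 0), `s_bar`, `sw`, `n_used` (named, per population), `undefined`.
#' @export
rst <- function(d, pops, locus_id, pop_a, pop_b, max_n = 100, seed = 1) {
  loci <- attr(d, "loci")
  i <- match(locus_id, loci$locus_id)
  if (is.na(i)) stop("locus not present: ", locus_id)
  groups <- subsample_dosages(d[, i], pops, c(pop_a, pop_b), max_n, seed)
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("need >= 2 called samples per population at ", locus_id)
  }
  rst_from_groups(groups)
}

# seeded per-population subsample of called dosages; stable sample order
subsample_dosages <- function(x, pops, pop_labels, max_n, seed) {
  pops <- pops[names(pops) %in% names(x)]
  with_seed(seed, {
    lapply(stats::setNames(pop_labels, pop_labels), function(p) {
      ids <- names(pops)[pops == p]
      if (!length(ids)) stop("population absent: ", p)
      v <- x[ids]
      v <- v[!is.na(v)]
      if (length(v) > max_n) v <- v[sort(sample.int(length(v), max_n))]
      unname(v)
    })
  })
}

# plug-in variance decomposition over a list of dosage vectors
rst_from_groups <- function(groups) {
  ns <- vapply(groups, length, 0L)
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  s_bar <- mean((pooled - mean(pooled))^2)
  sw <- sum(vapply(groups, function(v) length(v) * mean((v - mean(v))^2), 0)) / n
  if (s_bar == 0) {
    return(list(rst = NA_real_, s_bar = 0, sw = 0, n_used = ns, undefined = TRUE))
  }
  list(rst = (s_bar - sw) / s_bar, s_bar = s_bar, sw = sw, n_used = ns,
       undefined = FALSE)
}

#' TRDS: 2-Wasserstein distance between two allele distributions
#'
#' Exact W2 for 1-D discrete distributions via the quantile-function
#' representation: `W2 = sqrt(integral over q in (0,1) of
#' (Qa(q) - Qb(q))^2 dq)`, evaluated segment-by-segment on the union of the
#' two CDFs' breakpoints (exact for step quantile functions). TRDS is 0 iff
#' the two distributions are identical.
#'
#' @param freq_a,freq_b named numeric vectors: names are repeat-unit values,
#'   entries are probabilities summing to 1.
#' @param squared return the squared distance W2^2 instead of W2.
#' @return non-negative scalar.
#' @export
trds <- function(freq_a, freq_b, squared = FALSE) {
  if (!length(freq_a) || !length(freq_b)) stop("empty allele distribution")
  norm_dist <- function(f) {
    v <- as.numeric(names(f))
    if (anyNA(v)) stop("allele distribution names must be numeric repeat units")
    if (abs(sum(f) - 1) > 1e-6) stop("allele distribution must sum to 1")
    o <- order(v)
    list(vals = v[o], cum = cumsum(as.numeric(f)[o] / sum(f)))
  }
  a <- norm_dist(freq_a)
  b <- norm_dist(freq_b)
  qs <- sort(unique(c(a$cum, b$cum)))
  qs <- qs[qs <= 1 + 1e-12]
  lo <- c(0, qs[-length(qs)])
  w <- qs - lo
  mid <- (lo + qs) / 2
  qa <- a$vals[pmin(length(a$vals), findInterval(mid, a$cum) + 1L)]
  qb <- b$vals[pmin(length(b$vals), findInterval(mid, b$cum) + 1L)]
  val <- sum(w * (qa - qb)^2)
  if (squared) val else sqrt(val)
}

#' Empirical allele distribution of a population at one locus
#'
#' @param g StrGenotypes.
#' @param locus_id locus.
#' @param sample_ids samples to pool (both alleles per called sample).
#' @return named frequency vector (names = repeat units).
#' @export
allele_distribution <- function(g, locus_id, sample_ids = g$samples) {
  i <- match(locus_id, g$loci$locus_id)
  if (is.na(i)) stop("locus not present: ", locus_id)
  si <- match(sample_ids, g$samples)
  if (anyNA(si)) stop("unknown sample id")
  al <- c(g$a1[i, si], g$a2[i, si])
  al <- al[!is.na(al)]
  if (!length(al)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(al)
  stats::setNames(as.numeric(tab) / length(al), names(tab))
}

#' Per-locus divergence scan over population pairs
#'
#' Computes Rst and TRDS for every hypervariable locus (expected
#' heterozygosity > `het_floor`) and every requested population pair, with
#' per-pair subsampling to `max_n`. Loci whose pooled dosage variance is 0
#' are flagged undefined and excluded from summaries.
#'
#' @param g StrGenotypes.
#' @param pops named population vector.
#' @param pairs list of 2-vectors of population labels; default all pairs.
#' @param het_floor hypervariability gate (default 0.1).
#' @param max_n subsample cap (default 100).
#' @param seed RNG seed.
#' @param summaries optional precomputed [summarize_loci()] output.
#' @return data.frame: locus_id, pop_a, pop_b, rst, trds, n_a, n_b, undefined.
#' @export
divergence_scan <- function(g, pops, pairs = NULL, het_floor = 0.1,
                            max_n = 100, seed = 1, summaries = NULL) {
  stopifnot(inherits(g, "StrGenotypes"))
  if (is.null(summaries)) summaries <- summarize_loci(g)
  keep <- summaries$locus_id[!is.na(summaries$heterozygosity) &
                               summaries$heterozygosity > het_floor]
  labs <- unique(pops[g$samples])
  if (is.null(pairs)) {
    pairs <- utils::combn(labs, 2, simplify = FALSE)
  }
  d <- dosage_matrix(g)
  out <- list()
  for (pr in pairs) {
    for (id in keep) {
      i <- match(id, g$loci$locus_id)
      groups <- subsample_dosages(d[, i], pops, pr, max_n,
                                  derive_seed(seed, paste(pr, collapse = "_")))
      if (any(vapply(groups, length, 0L) < 2)) next
      r <- rst_from_groups(groups)
      ids_a <- names(pops)[pops == pr[1]]
      ids_b <- names(pops)[pops == pr[2]]
      fa <- allele_distribution(g, id, intersect(ids_a, g$samples))
      fb <- allele_distribution(g, id, intersect(ids_b, g$samples))
      out[[length(out) + 1L]] <- data.frame(
        locus_id = id, pop_a = pr[1], pop_b = pr[2],
        rst = r$rst, trds = trds(fa, fb),
        n_a = r$n_used[[1]], n_b = r$n_used[[2]],
        undefined = r$undefined, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(locus_id = character(0), pop_a = character(0),
                      pop_b = character(0), rst = numeric(0), trds = numeric(0),
                      n_a = integer(0), n_b = integer(0), undefined = logical(0)))
  }
  do.call(rbind, out)
}

#' Classify divergent loci from a divergence scan
#'
#' A locus is divergent when its maximum defined Rst over the scanned
#' population pairs exceeds the threshold; tiers are reported at 0.1
#' (divergent) and 0.2 (tightened).
#'
#' @param records data.frame from [divergence_scan()].
#' @param threshold Rst threshold for the main call (default 0.1).
#' @return data.frame: locus_id, max_rst, divergent, tier
#'   (`"none"`, `">0.1"`, `">0.2"`).
#' @export
divergent_loci <- function(records, threshold = 0.1) {
  rec <- records[!records$undefined & !is.na(records$rst), , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(locus_id = character(0), max_rst = numeric(0),
                      divergent = logical(0), tier = character(0)))
  }
  mx <- tapply(rec$rst, rec$locus_id, max)
  data.frame(
    locus_id = names(mx),
    max_rst = as.numeric(mx),
    divergent = as.numeric(mx) > threshold,
    tier = ifelse(mx > 0.2, ">0.2", ifelse(mx > 0.1, ">0.1", "none")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
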