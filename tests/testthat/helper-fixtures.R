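# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops / brute force so they share no code path with the package.

# small hand-built genotype set: 2 loci x 3 samples, one missing call
toy_genotypes <- function() {
  loci <- data.frame(
    locus_id = c("L1", "L2"), chrom = c("chr1", "chr1"),
    pos_start = c(100L, 5000L), pos_end = c(130L, 5040L),
    motif = c("AT", "AGC"), ref_units = c(15L, 13L),
    stringsAsFactors = FALSE
  )
  a1 <- rbind(c(10, 10, 12), c(8, NA, 9))
  a2 <- rbind(c(12, 10, 14), c(9, NA, 9))
  str_genotypes(loci, c("S1", "S2", "S3"), a1, a2)
}

# genotypes where every call at every locus equals `units`
constant_genotypes <- function(n_loci = 3, samples = c("A1", "A2"), units = 10,
                               motif = "AGC") {
  loci <- data.frame(
    locus_id = paste0("C", seq_len(n_loci)), chrom = "chr1",
    pos_start = seq_len(n_loci) * 1000L,
    pos_end = seq_len(n_loci) * 1000L + 30L,
    motif = motif, ref_units = units, stringsAsFactors = FALSE
  )
  m <- matrix(units, n_loci, length(samples))
  str_genotypes(loci, samples, m, m)
}

# build genotypes from an explicit allele-pair list: alleles[[sample]] = c(a1, a2)
genotypes_from_pairs <- function(pairs_per_sample, motif = "AGC", n_copies = 1) {
  samples <- names(pairs_per_sample)
  a1 <- matrix(vapply(pairs_per_sample, `[`, 0, 1L), 1)
  a2 <- matrix(vapply(pairs_per_sample, `[`, 0, 2L), 1)
  loci <- data.frame(locus_id = "LX", chrom = "chr1", pos_start = 100L,
                     pos_end = 150L, motif = motif, ref_units = 10L,
                     stringsAsFactors = FALSE)
  str_genotypes(loci, samples, a1, a2)
}

# --- oracles ---------------------------------------------------------------

# brute-force Rst: explicit plug-in variance decomposition with loops
oracle_rst <- function(groups) {
  all_v <- c()
  for (g in groups) all_v <- c(all_v, g)
  gm <- sum(all_v) / length(all_v)
  s_bar <- 0
  for (v in all_v) s_bar <- s_bar + (v - gm)^2
  s_bar <- s_bar / length(all_v)
  sw <- 0
  for (g in groups) {
    m <- sum(g) / length(g)
    ss <- 0
    for (v in g) ss <- ss + (v - m)^2
    sw <- sw + ss
  }
  sw <- sw / length(all_v)
  (s_bar - sw) / s_bar
}

# numeric quantile-integration W2 on a fine grid (independent of the
# breakpoint-merge evaluation in the package). Exact when both distributions
# have weights that are multiples of 1/denominator and n_grid is a multiple
# of the denominator: the step quantile functions are then constant within
# every grid cell, so midpoint evaluation integrates them exactly.
oracle_w2_grid <- function(freq_a, freq_b, n_grid = 8400) {
  qfun <- function(f, q) {
    v <- as.numeric(names(f))
    o <- order(v)
    v <- v[o]; cum <- cumsum(f[o] / sum(f))
    v[pmin(length(v), findInterval(q, cum - 1e-12) + 1L)]
  }
  qs <- (seq_len(n_grid) - 0.5) / n_grid
  sqrt(mean((qfun(freq_a, qs) - qfun(freq_b, qs))^2))
}

# sorted-array percentile with linear interpolation, written independently
oracle_p95 <- function(x) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * 0.95 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# independent MI validity predicate (vectorized)
oracle_mi_valid <- function(c1, c2, f1, f2, m1, m2) {
  ((c1 == f1 | c1 == f2) & (c2 == m1 | c2 == m2)) |
    ((c2 == f1 | c2 == f2) & (c1 == m1 | c1 == m2))
}

# brute-force interval overlap: all-pairs scan
oracle_overlaps <- function(q_chrom, q_start, q_end, m_chrom, m_start, m_end) {
  hit <- logical(length(q_start))
  for (i in seq_along(q_start)) {
    for (j in seq_along(m_start)) {
      if (q_chrom[i] == m_chrom[j] &&
          q_start[i] <= m_end[j] && q_end[i] >= m_start[j]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

# enumeration HWE exact test on collapsed biallelic counts
oracle_hwe <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
  prob <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- n - aa - h
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) - lchoose(2 * n, nA))
  }, 0)
  # normalize (the conditional distribution sums to 1)
  prob <- prob / sum(prob)
  obs <- prob[match(nAB, hets)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# random allele-frequency distribution over integer support; weights are
# counts over a fixed denominator (as empirical allele frequencies are), so
# that the aligned-grid oracle is exact
random_freq <- function(max_support = 6, lo = 5, hi = 40, denom = 84) {
  k <- sample(seq_len(max_support), 1)
  vals <- sort(sample(lo:hi, k))
  counts <- as.vector(stats::rmultinom(1, denom, rep(1, k)))
  keep <- counts > 0
  stats::setNames(counts[keep] / denom, vals[keep])
}
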