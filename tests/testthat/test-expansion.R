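# genotype set with one locus per row of an allele-spec list; every sample
# homozygous so population allele spectra are easy to state exactly
profile_genotypes <- function(alleles_by_pop, motif = "AGC") {
  pops_labels <- names(alleles_by_pop)
  n <- vapply(alleles_by_pop, length, 0L)
  samples <- unlist(lapply(pops_labels, function(p) paste0(p, "_", seq_len(n[[p]]))))
  vals <- unlist(alleles_by_pop, use.names = FALSE)
  loci <- data.frame(locus_id = "PX", chrom = "chr1", pos_start = 100L,
                     pos_end = 160L, motif = motif, ref_units = 20L,
                     stringsAsFactors = FALSE)
  g <- str_genotypes(loci, samples, matrix(vals, 1), matrix(vals, 1))
  pops <- stats::setNames(rep(pops_labels, n), samples)
  list(g = g, pops = pops)
}

test_that("outlier criteria reproduce hand-computed decisions", {
  # 20 hand-worked cases: (major, allele, motif_len) -> outlier?
  cases <- data.frame(
    major = c(20, 20, 30, 30, 18, 18, 12, 12, 40, 40,
              20, 22, 14, 50, 8, 16, 24, 10, 35, 28),
    allele = c(31, 29, 42, 45, 30, 27, 24, 23, 60, 49,
               9, 44, 29, 24, 20, 33, 36, 21, 53, 14),
    motif_len = c(3, 3, 4, 4, 3, 3, 3, 3, 5, 5,
                  3, 2, 3, 3, 3, 4, 3, 3, 4, 3),
    stringsAsFactors = FALSE
  )
  # criteria: motif >= 3; |delta| >= 10; |delta| >= 0.5 * major
  expected <- with(cases, motif_len >= 3 & abs(allele - major) >= 10 &
                     abs(allele - major) >= 0.5 * major)
  for (i in seq_len(nrow(cases))) {
    motif <- strrep("ACG", 1)
    motif <- c("AT", "ACG", "ACGT", "ACGTA")[match(cases$motif_len[i], c(2, 3, 4, 5))]
    # population of 20 at the major allele plus one carrier of the test allele
    fx <- profile_genotypes(list(P = c(rep(cases$major[i], 20), cases$allele[i])),
                            motif = motif)
    rep_out <- find_outlier_alleles(fx$g, fx$pops)
    expect_equal(nrow(rep_out) == 1, expected[i],
                 label = sprintf("case %d (major %d, allele %d, motif %d)",
                                 i, cases$major[i], cases$allele[i], cases$motif_len[i]))
    if (expected[i]) {
      expect_equal(rep_out$direction,
                   if (cases$allele[i] > cases$major[i]) "expanded" else "contracted")
    }
  }
})

test_that("removing any single criterion strictly enlarges the outlier set", {
  set.seed(77)
  # seeded random cohort with a mix of motif lengths and long alleles
  n_loci <- 40
  loci <- data.frame(
    locus_id = sprintf("R%03d", seq_len(n_loci)), chrom = "chr1",
    pos_start = seq_len(n_loci) * 500L, pos_end = seq_len(n_loci) * 500L + 50L,
    motif = sample(c("AT", "ACG", "ACGT"), n_loci, TRUE),
    ref_units = 20L, stringsAsFactors = FALSE
  )
  samples <- sprintf("S%03d", 1:40)
  a1 <- matrix(sample(c(10:30, 45:60), n_loci * 40, TRUE,
                      prob = c(rep(8, 21), rep(1, 16))), n_loci, 40)
  g <- str_genotypes(loci, samples, a1, a1)
  pops <- stats::setNames(rep("P1", 40), samples)
  full <- find_outlier_alleles(g, pops)
  # relaxed reimplementations dropping one criterion each
  count_relaxed <- function(drop) {
    hits <- 0
    for (l in seq_len(n_loci)) {
      al <- c(g$a1[l, ], g$a2[l, ]); al <- al[!is.na(al)]
      tab <- table(al); units <- as.numeric(names(tab))
      major <- units[order(-as.numeric(tab), units)][1]
      delta <- abs(units - major)
      c1 <- nchar(loci$motif[l]) >= 3
      c2 <- delta >= 10
      c3 <- delta >= 0.5 * major
      keep <- switch(drop,
                     none = c1 & c2 & c3, motif = c2 & c3,
                     ten = c1 & c3, half = c1 & c2)
      hits <- hits + sum(keep)
    }
    hits
  }
  base <- count_relaxed("none")
  expect_equal(nrow(full), base)
  for (drop in c("motif", "ten", "half")) expect_gt(count_relaxed(drop), base)
})

test_that("expansion score matches its arithmetic and the percentile oracle", {
  expect_equal(expansion_score(rep(10, 30)), 0)
  # median 10, p95 30 -> score 2
  x <- c(rep(10, 99), 30)
  x95 <- stats::quantile(x, 0.95, names = FALSE)
  expect_equal(expansion_score(x), (x95 - 10) / 10)
  set.seed(13)
  for (i in 1:500) {
    v <- sample(5:80, sample(10:120, 1), replace = TRUE)
    med <- stats::median(v)
    expect_lt(abs(expansion_score(v) - (oracle_p95(v) - med) / med), 1e-9)
  }
  # scale covariance: multiplying lengths by c > 0 leaves the score unchanged
  v <- c(10, 11, 12, 14, 40, 41)
  expect_equal(expansion_score(v * 7), expansion_score(v), tolerance = 1e-12)
})

test_that("expansion profile retains loci by max score and emits aligned CVs", {
  fx <- profile_genotypes(list(
    A = c(rep(10, 90), rep(40, 10)),
    B = rep(10, 100)
  ))
  prof <- expansion_profile(fx$g, fx$pops, score_floor = 2)
  expect_equal(rownames(prof$scores), "PX")
  expect_gte(prof$scores["PX", "A"], 2)
  expect_lt(prof$scores["PX", "B"], 2)
  # identical populations: equal CV columns
  fx2 <- profile_genotypes(list(A = c(10, 12, 40, 10), B = c(10, 12, 40, 10)))
  prof2 <- expansion_profile(fx2$g, fx2$pops, score_floor = 0)
  expect_equal(prof2$cv[, "A"], prof2$cv[, "B"])
  # infinite floor: empty profile
  prof3 <- expansion_profile(fx$g, fx$pops, score_floor = Inf)
  expect_equal(nrow(prof3$scores), 0L)
})

test_that("planted single-population expansions are seen only in that population", {
  sim <- simulate_cohort(sim_config(n_populations = 3, n_per_pop = 50,
                                    n_loci = 30, seed = 91))
  target <- sim$genotypes$loci$locus_id[nchar(sim$genotypes$loci$motif) >= 3][1]
  inj <- inject_expansions(sim$genotypes, sim$pops, target, "POP2",
                           carrier_frac = 0.3, target_units = 60, seed = 92)
  prof <- expansion_profile(inj$genotypes, sim$pops, score_floor = 2)
  expect_true(target %in% rownames(prof$scores))
  sc <- prof$scores[target, ]
  expect_gte(sc[["POP2"]], 2)
  expect_true(all(sc[c("POP1", "POP3")] < 2))
})

test_that("length difference test: ties give p near 1, planted shifts are outliers", {
  fx <- profile_genotypes(list(A = rep(12, 30), B = rep(12, 30)))
  out <- length_difference_test(fx$g, fx$pops, "A", "B")
  expect_equal(out$fold_change, 1)
  expect_false(out$outlier)
  # planted +5 repeat shift at 200 alleles per group
  fx2 <- profile_genotypes(list(A = rep(c(15, 16, 17, 18), 25),
                                B = rep(c(20, 21, 22, 23), 25)))
  out2 <- length_difference_test(fx2$g, fx2$pops, "A", "B")
  expect_lt(out2$q, 0.05)
  expect_true(out2$outlier)
  expect_lt(out2$fold_change, 1)
})

test_that("BH adjustment matches its arithmetic", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.5), "BH"), c(0.03, 0.03, 0.5))
})

test_that("pathogenic TRDS null: gross shifts flagged, pathogenic alleles counted", {
  set.seed(14)
  # cohort of 600; population P1 is shifted +15 repeats at the locus
  n <- 600
  base <- sample(10:14, n, TRUE)
  vals <- base
  vals[1:60] <- base[1:60] + 15
  samples <- sprintf("S%03d", seq_len(n))
  loci <- data.frame(locus_id = "PATH1", chrom = "chr1", pos_start = 100L,
                     pos_end = 160L, motif = "CAG", ref_units = 12L,
                     stringsAsFactors = FALSE)
  g <- str_genotypes(loci, samples, matrix(vals, 1), matrix(vals, 1))
  pops <- stats::setNames(c(rep("P1", 60), rep("P2", n - 60)), samples)
  out <- pathogenic_trds_null(g, pops, "PATH1", pathogenic_threshold = 20,
                              n_control = 500, reps = 100, seed = 15)
  expect_true(out$flagged[out$population == "P1"])
  # the shifted population deviates far more than its complement
  expect_gt(out$trds_observed[out$population == "P1"],
            2 * out$trds_observed[out$population == "P2"])
  # threshold 15 with alleles (12, 16, 20): two pathogenic-range alleles
  g2 <- genotypes_from_pairs(list(S1 = c(12, 16), S2 = c(20, 20)))
  p2 <- stats::setNames(c("Q", "Q"), c("S1", "S2"))
  out2 <- pathogenic_trds_null(g2, p2, "LX", pathogenic_threshold = 15,
                               n_control = 2, reps = 20, seed = 16)
  expect_equal(out2$n_pathogenic_alleles, 3L)  # 16, 20, 20
  out3 <- pathogenic_trds_null(g2, p2, "LX", pathogenic_threshold = 19,
                               n_control = 2, reps = 20, seed = 16)
  expect_equal(out3$n_pathogenic_alleles, 2L)  # the two 20s
})

test_that("random pseudo-populations are rarely flagged by the TRDS null", {
  set.seed(17)
  n <- 400
  vals <- sample(8:20, n, TRUE)
  samples <- sprintf("S%03d", seq_len(n))
  loci <- data.frame(locus_id = "PATH2", chrom = "chr1", pos_start = 100L,
                     pos_end = 160L, motif = "CTG", ref_units = 12L,
                     stringsAsFactors = FALSE)
  g <- str_genotypes(loci, samples, matrix(vals, 1), matrix(vals, 1))
  flags <- vapply(1:40, function(r) {
    idx <- sample(n, 50)
    pops <- stats::setNames(ifelse(seq_len(n) %in% idx, "PP", "REST"), samples)
    out <- pathogenic_trds_null(g, pops, "PATH2", pathogenic_threshold = 25,
                                n_control = 300, reps = 60, seed = 100 + r)
    out$flagged[out$population == "PP"]
  }, NA)
  expect_lte(mean(flags), 0.05 + 2 * sqrt(0.05 * 0.95 / 40))
})
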