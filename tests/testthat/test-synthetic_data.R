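test_that("the generator is deterministic under its seed", {
  a <- simulate_cohort(sim_config(n_per_pop = 15, n_loci = 30, seed = 1))
  b <- simulate_cohort(sim_config(n_per_pop = 15, n_loci = 30, seed = 1))
  c <- simulate_cohort(sim_config(n_per_pop = 15, n_loci = 30, seed = 2))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth$divergent, b$truth$divergent)
  expect_false(identical(a$genotypes$a1, c$genotypes$a1))
})

test_that("degenerate configs are rejected", {
  expect_error(sim_config(n_loci = 0), "degenerate")
  expect_error(sim_config(n_per_pop = 0), "degenerate")
  expect_error(sim_config(mu = -1), "mu")
  expect_error(sim_config(beta_exp = 1.5), "rates")
})

test_that("zero drift and zero mutation give degenerate downstream statistics", {
  cfg <- sim_config(n_populations = 3, n_per_pop = 50, n_loci = 25,
                    mu = 0, generations = 0, within_generations = 0,
                    divergent_frac = 0, founder_chromosomes = 10000, seed = 5)
  sim <- simulate_cohort(cfg)
  div <- divergence_scan(sim$genotypes, sim$pops, seed = 3)
  # populations share the ancestral distribution: Rst near 0, defined or flagged
  expect_lt(mean(div$rst[!div$undefined]), 0.05)
  # allele distributions close, TRDS small; identical subsets give exactly 0
  id <- div$locus_id[1]
  fa <- allele_distribution(sim$genotypes, id)
  expect_identical(trds(fa, fa), 0)
  # expansion score of a constant locus is 0
  expect_identical(expansion_score(rep(12, 50)), 0)
})

test_that("two populations fixed for different alleles give Rst = 1", {
  loci <- data.frame(locus_id = "F1", chrom = "chr1", pos_start = 1L,
                     pos_end = 60L, motif = "AGC", ref_units = 10L,
                     stringsAsFactors = FALSE)
  samples <- sprintf("S%02d", 1:20)
  units <- rep(c(10, 20), each = 10)
  g <- str_genotypes(loci, samples, matrix(units, 1), matrix(units, 1))
  pops <- stats::setNames(rep(c("A", "B"), each = 10), samples)
  r <- rst(dosage_matrix(g), pops, "F1", "A", "B", seed = 1)
  expect_equal(r$rst, 1)
})

test_that("estimated Rst increases monotonically with drift generations", {
  gens <- c(0, 1000, 4000, 16000)
  means <- vapply(gens, function(gn) {
    sim <- simulate_cohort(sim_config(
      n_populations = 2, n_per_pop = 80, n_loci = 60, generations = gn,
      divergent_frac = 0, seed = 11
    ))
    dv <- divergence_scan(sim$genotypes, sim$pops, seed = 3)
    mean(dv$rst[!dv$undefined])
  }, 0)
  expect_identical(cor(gens, means, method = "spearman"), 1)
})

test_that("expression generator plants recoverable effects with known covariates", {
  sim <- simulate_cohort(sim_config(n_populations = 2, n_per_pop = 100,
                                    n_loci = 60, seed = 21))
  d <- dosage_matrix(sim$genotypes)
  ex <- simulate_expression(d, sim$pops, n_genes = 30, causal_frac = 0.5,
                            beta_true = 0.8, sigma = 1, seed = 22)
  expect_equal(dim(ex$expr), c(200L, 30L))
  expect_equal(rownames(ex$covariates), rownames(d))
  causal <- ex$truth[ex$truth$beta_true != 0, ]
  expect_gt(nrow(causal), 5)
  # direct regression on the causal locus recovers the planted sign
  hits <- 0
  for (i in seq_len(nrow(causal))) {
    x <- zscore(d[, causal$locus_id[i]])
    fit <- stats::lm(ex$expr[, causal$gene_id[i]] ~ x + ex$covariates)
    if (coef(fit)[["x"]] > 0) hits <- hits + 1
  }
  expect_gte(hits / nrow(causal), 0.9)
})

test_that("environment generator builds the stated gradient structure", {
  sim <- simulate_cohort(sim_config(n_populations = 3, n_per_pop = 60,
                                    n_loci = 50, seed = 31))
  es <- simulate_environment(sim$genotypes, sim$pops, effect_frac = 0.1, seed = 32)
  # altitude/temperature correlation is negative by construction
  expect_lt(cor(es$env$altitude_m, es$env$temp_c_annual_mean), 0)
  # loci with planted effects show dosage-altitude correlation; others don't
  d <- dosage_matrix(es$genotypes)
  alt <- es$env$altitude_m[match(rownames(d), es$env$sample_id)]
  r_eff <- abs(vapply(which(es$truth), function(l) cor(d[, l], alt, use = "complete.obs"), 0))
  r_null <- abs(vapply(which(!es$truth), function(l) cor(d[, l], alt, use = "complete.obs"), 0))
  expect_gt(mean(r_eff), mean(r_null))
  expect_gt(mean(r_eff), 0.3)
})

test_that("trio generator: rate 0 gives MI 1.0; forced mutation breaks one trio-locus", {
  sim <- simulate_cohort(sim_config(n_populations = 2, n_per_pop = 30,
                                    n_loci = 40, seed = 41))
  tr <- simulate_trios(sim$genotypes, n_trios = 8, mutation_rate = 0, seed = 42)
  mi <- mendelian_consistency(tr$genotypes, tr$trios)
  expect_equal(mi$rate, 1.0)
  expect_null(tr$truth)

  # 1 trio, 1 locus, forced mutation: make parents monomorphic so any step breaks MI
  loci <- data.frame(locus_id = "T1", chrom = "chr1", pos_start = 1L,
                     pos_end = 60L, motif = "AGC", ref_units = 10L,
                     stringsAsFactors = FALSE)
  gp <- str_genotypes(loci, c("P1", "P2"), matrix(c(10, 10), 1), matrix(c(10, 10), 1))
  tf <- simulate_trios(gp, n_trios = 1, mutation_rate = 1, seed = 43)
  expect_equal(mendelian_consistency(tf$genotypes, tf$trios)$rate, 0)
})

test_that("planted trio mutations match their binomial expectation", {
  sim <- simulate_cohort(sim_config(n_populations = 2, n_per_pop = 60,
                                    n_loci = 300, seed = 51))
  rate <- 0.02
  tr <- simulate_trios(sim$genotypes, n_trios = 20, mutation_rate = rate, seed = 52)
  n_transmissions <- 2 * 20 * 300
  observed <- sum(tr$truth$paternal) + sum(tr$truth$maternal)
  expected <- n_transmissions * rate
  se <- sqrt(n_transmissions * rate * (1 - rate))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("injected expansions create carriers only in the target population", {
  sim <- simulate_cohort(sim_config(n_populations = 2, n_per_pop = 40,
                                    n_loci = 30, seed = 61))
  target <- sim$genotypes$loci$locus_id[nchar(sim$genotypes$loci$motif) >= 3][1]
  inj <- inject_expansions(sim$genotypes, sim$pops, target, "POP2",
                           carrier_frac = 0.25, target_units = 50, seed = 62)
  carriers <- inj$truth$sample
  expect_true(all(sim$pops[carriers] == "POP2"))
  l <- match(target, inj$genotypes$loci$locus_id)
  cols <- match(carriers, inj$genotypes$samples)
  expect_true(all(inj$genotypes$a2[l, cols] == 50))
})

test_that("planted SNP-STR correlations land near their targets", {
  sim <- simulate_cohort(sim_config(n_populations = 2, n_per_pop = 150,
                                    n_loci = 40, seed = 71))
  d <- dosage_matrix(sim$genotypes)
  sn <- simulate_snps(d, n_snps = 40, r_at_zero = 0.9, r_at_window = 0.1, seed = 72)
  r_obs <- vapply(seq_len(40), function(j) {
    cor(sn$snp_dosage[, j], d[, sn$truth$locus_id[j]], use = "complete.obs")
  }, 0)
  # thresholding attenuates the latent correlation; demand a strong rank link
  expect_gt(cor(abs(r_obs), sn$truth$target_r, method = "spearman"), 0.6)
})
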