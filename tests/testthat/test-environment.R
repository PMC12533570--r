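env_design <- function(n_loci, n_samples, seed, effect = 0) {
  set.seed(seed)
  loci <- data.frame(
    locus_id = sprintf("E%04d", seq_len(n_loci)), chrom = "chr1",
    pos_start = seq_len(n_loci) * 1000L, pos_end = seq_len(n_loci) * 1000L + 40L,
    motif = "AGC", ref_units = 12L, stringsAsFactors = FALSE
  )
  samples <- sprintf("S%04d", seq_len(n_samples))
  alt <- stats::runif(n_samples, 0, 4500)
  d <- matrix(sample(16:44, n_loci * n_samples, TRUE), n_samples, n_loci,
              dimnames = list(samples, loci$locus_id))
  if (effect != 0) d <- d + outer(round(effect * zscore(alt)), rep(1, n_loci))
  d <- structure(d, loci = loci, class = c("DosageMatrix", "matrix", "array"))
  env <- data.frame(sample_id = samples, altitude_m = alt,
                    temp_c_annual_mean = 22 - 0.005 * alt + stats::rnorm(n_samples),
                    solar_kj_m2_day = 15000 + 2 * alt + stats::rnorm(n_samples, 0, 500),
                    stringsAsFactors = FALSE)
  list(d = d, env = env)
}

test_that("null environment scan gives uniform p-values per variable", {
  dz <- env_design(250, 200, seed = 2)
  panel <- env_scan(dz$d, dz$env)
  expect_setequal(unique(panel$variable), c("altitude", "inv_temp", "solar"))
  for (v in unique(panel$variable)) {
    ks <- stats::ks.test(panel$p[panel$variable == v], "punif")
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("a planted altitude effect is detected with the right sign", {
  dz <- env_design(60, 300, seed = 3, effect = 3)
  panel <- env_scan(dz$d, dz$env)
  alt <- panel[panel$variable == "altitude", ]
  sig <- alt[alt$p < 0.05, ]
  expect_gt(nrow(sig), 40)
  expect_gte(mean(sig$beta > 0), 0.99)
})

test_that("a duplicated variable yields identical columns; constants error", {
  dz <- env_design(20, 80, seed = 4)
  env2 <- dz$env
  env2$altitude_copy <- env2$altitude_m
  panel <- env_scan(dz$d, env2)
  a <- panel[panel$variable == "altitude", c("beta", "se", "p")]
  b <- panel[panel$variable == "altitude_copy", c("beta", "se", "p")]
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)))
  env3 <- dz$env
  env3$solar_kj_m2_day <- 12000
  expect_error(env_scan(dz$d, env3), "constant environment variable: solar")
})

test_that("EB shrinkage: zero noise means no shrinkage; symmetry gives the common value", {
  panel <- data.frame(
    locus_id = rep(sprintf("L%02d", 1:12), each = 3),
    variable = rep(c("altitude", "inv_temp", "solar"), 12),
    beta = rep(stats::rnorm(12, 0, 0.5), each = 3),
    se = 1e-9, stringsAsFactors = FALSE
  )
  cpm <- combine_effects(panel)
  expect_equal(cpm$cpm, panel$beta[seq(1, 36, by = 3)], tolerance = 1e-6)
  # identical beta across variables with equal se: CPM equals the common posterior mean
  panel$se <- 0.3
  cpm2 <- combine_effects(panel)
  expect_equal(cpm2$cpm, cpm2$pm_altitude, tolerance = 1e-12)
})

test_that("shrinkage contract: |posterior mean| <= |beta|, vanishing as se grows", {
  set.seed(9)
  mk <- function(se) data.frame(
    locus_id = sprintf("L%03d", 1:200), variable = "altitude",
    beta = stats::rnorm(200, 0, 0.4), se = se, stringsAsFactors = FALSE
  )
  p_small <- mk(0.01); p_big <- mk(50)
  c_small <- combine_effects(p_small)
  c_big <- combine_effects(p_big)
  expect_true(all(abs(c_small$cpm) <= abs(p_small$beta) + 1e-12))
  expect_equal(c_small$cpm, p_small$beta, tolerance = 0.01)
  expect_true(all(abs(c_big$cpm) < 0.05))
})

test_that("method-of-moments recovers the between-locus effect variance", {
  set.seed(10)
  tau <- 0.3; se <- 0.2; n <- 5000
  beta_hat <- stats::rnorm(n, 0, sqrt(tau^2 + se^2))
  panel <- data.frame(locus_id = sprintf("L%05d", 1:n), variable = "altitude",
                      beta = beta_hat, se = se, stringsAsFactors = FALSE)
  t2 <- attr(combine_effects(panel), "tau2")[["altitude"]]
  expect_lt(abs(t2 - tau^2) / tau^2, 0.2)
})

test_that("fewer than 10 loci falls back to raw means with a warning", {
  panel <- data.frame(locus_id = c("A", "B"), variable = "altitude",
                      beta = c(0.5, -0.2), se = 0.1, stringsAsFactors = FALSE)
  expect_warning(cpm <- combine_effects(panel), "fewer than 10")
  expect_equal(cpm$cpm, c(0.5, -0.2))
})

test_that("Fisher combination matches the chi-square closed form", {
  # one test: identity
  p1 <- fisher_combine(data.frame(locus_id = "A", p = 0.05))
  expect_equal(p1$fisher_p, 0.05, tolerance = 1e-12)
  # three p-values of 0.5: chi2 = 4.159, p ~ 0.655 on 6 df
  p3 <- fisher_combine(data.frame(locus_id = rep("A", 3), p = 0.5))
  expect_equal(p3$chi2, -2 * 3 * log(0.5), tolerance = 1e-3)
  expect_equal(round(p3$chi2, 3), 4.159)
  expect_equal(p3$fisher_p, stats::pchisq(4.158883, df = 6, lower.tail = FALSE),
               tolerance = 1e-6)
  # closed-form agreement within 1e-10 on random panels
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    ps <- stats::runif(k)
    out <- fisher_combine(data.frame(locus_id = rep("X", k), p = ps))
    expect_lt(abs(out$fisher_p -
                    stats::pchisq(-2 * sum(log(ps)), 2 * k, lower.tail = FALSE)), 1e-10)
  }
  # monotone limit: any p -> 0 drives the combination to 0
  tiny <- fisher_combine(data.frame(locus_id = rep("A", 3), p = c(1e-300, 0.5, 0.9)))
  expect_lt(tiny$fisher_p, 1e-290)
})

test_that("hSTR calling is the strict conjunction of CPM and Fisher thresholds", {
  cpm_tab <- data.frame(locus_id = c("A", "B", "C", "D"),
                        cpm = c(0.29, 0.5, -0.4, 0.6), stringsAsFactors = FALSE)
  fish <- data.frame(locus_id = c("A", "B", "C", "D"),
                     fisher_p = c(1e-4, 0.15, 0.005, 0.001),
                     fisher_p_bh = c(0.001, 0.2, 0.01, 0.004),
                     stringsAsFactors = FALSE)
  h <- call_hstr(cpm_tab, fish)
  expect_equal(h$is_hstr[h$locus_id == "A"], FALSE)  # CPM 0.29 below 0.3
  expect_equal(h$is_hstr[h$locus_id == "B"], FALSE)  # p_bh 0.2 above alpha
  expect_equal(h$is_hstr[h$locus_id == "C"], TRUE)   # |-0.4| > 0.3 and p ok
  expect_equal(h$is_hstr[h$locus_id == "D"], TRUE)
})

test_that("hSTR call rate under the global null stays at or below alpha", {
  rate <- vapply(1:8, function(r) {
    dz <- env_design(150, 150, seed = 100 + r)
    panel <- env_scan(dz$d, dz$env)
    h <- call_hstr(combine_effects(panel), fisher_combine(panel))
    mean(h$is_hstr)
  }, 0)
  expect_lte(mean(rate), 0.05)
})

test_that("CPM-Rst correlation handles planted, degenerate, and identity cases", {
  # planted: larger |cpm| paired with larger rst
  set.seed(12)
  n <- 200
  ids <- sprintf("L%03d", 1:n)
  rst_v <- stats::runif(n, 0, 0.8)
  cpm_v <- (0.31 + rst_v) * sample(c(-1, 1), n, TRUE)
  hstr_tab <- data.frame(locus_id = ids, cpm = cpm_v,
                         fisher_p_bh = 0.001, is_hstr = TRUE,
                         stringsAsFactors = FALSE)
  rec <- data.frame(locus_id = ids, pop_a = "A", pop_b = "B", rst = rst_v,
                    trds = 1, n_a = 50L, n_b = 50L, undefined = FALSE,
                    stringsAsFactors = FALSE)
  out <- cpm_rst_correlation(hstr_tab, rec)
  expect_gt(out$r, 0.9)
  expect_lt(out$p, 0.05)
  # |CPM| against a copy of itself: r = 1
  rec2 <- rec; rec2$rst <- abs(cpm_v)
  expect_equal(cpm_rst_correlation(hstr_tab, rec2)$r, 1, tolerance = 1e-12)
  # constant Rst: flagged undefined
  rec3 <- rec; rec3$rst <- 0.5
  expect_true(cpm_rst_correlation(hstr_tab, rec3)$undefined)
})
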