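#' Configuration for the synthetic STR cohort generator
#'
#' Defaults describe a small multi-population cohort with the statistical
#' structure the downstream analyses assume: populations descending from a
#' shared ancestral allele pool under a truncated stepwise mutation model
#' (SMM) with per-population drift, a subset of extra-drifted "divergent"
#' loci, planted cis expression effects, population-confounded environment
#' gradients, trios with a known transmission mutation rate, and injected
#' long-allele expansions.
#'
#' @param n_populations number of population groups.
#' @param n_per_pop samples per population.
#' @param n_loci number of STR loci.
#' @param motif_lengths motif lengths sampled for loci (2-6 bp).
#' @param motif_probs sampling weights for `motif_lengths` (di- and
#'   tetranucleotide repeats dominate polymorphic catalogs).
#' @param ancestral_mean,ancestral_sd mean and SD of the ancestral
#'   repeat-unit distribution (discretized normal, floored at 2).
#' @param mu SMM mutation rate per lineage per generation.
#' @param generations per-population drift generations (recycled to
#'   `n_populations`): mutations fixed along the population's shared lineage
#'   shift its whole allele pool, producing between-population divergence
#'   that grows with this value.
#' @param within_generations generations of private (per-allele) mutation,
#'   adding within-population allele heterogeneity without divergence.
#' @param founder_chromosomes size of each population's founder allele pool;
#'   small pools create genuine allele-frequency drift between populations.
#' @param beta_exp probability that a mutation step is +1 rather than -1
#'   (default 0.524: expansions slightly outnumber contractions).
#' @param divergent_frac fraction of loci given extra drift.
#' @param divergent_extra_generations extra drift generations at divergent
#'   loci.
#' @param seed RNG seed; the same seed gives byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 3, n_per_pop = 60, n_loci = 300,
                       motif_lengths = 2:6,
                       motif_probs = c(0.35, 0.15, 0.35, 0.08, 0.07),
                       ancestral_mean = 15, ancestral_sd = 3,
                       mu = 0.001, generations = 200,
                       within_generations = 300,
                       founder_chromosomes = 150,
                       beta_exp = 0.524,
                       divergent_frac = 0.05,
                       divergent_extra_generations = 10000,
                       seed = 1) {
  if (n_populations < 1 || n_per_pop < 1 || n_loci < 1) {
    stop("degenerate config: populations, samples and loci must all be >= 1")
  }
  if (beta_exp < 0 || beta_exp > 1 || divergent_frac < 0 || divergent_frac > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (mu < 0) stop("mu must be >= 0")
  structure(list(
    n_populations = n_populations, n_per_pop = n_per_pop, n_loci = n_loci,
    motif_lengths = motif_lengths, motif_probs = motif_probs,
    ancestral_mean = ancestral_mean, ancestral_sd = ancestral_sd,
    mu = mu, generations = rep_len(generations, n_populations),
    within_generations = within_generations,
    founder_chromosomes = founder_chromosomes, beta_exp = beta_exp,
    divergent_frac = divergent_frac,
    divergent_extra_generations = divergent_extra_generations,
    seed = seed
  ), class = "sim_config")
}

# apply k ~ Poisson(rate) stepwise mutations to each allele, +1 w.p. beta_exp,
# floored at 1 repeat unit (truncated SMM)
smm_mutate <- function(alleles, rate, beta_exp) {
  if (rate <= 0) return(alleles)
  k <- stats::rpois(length(alleles), rate)
  has <- which(k > 0)
  for (i in has) {
    steps <- ifelse(stats::runif(k[i]) < beta_exp, 1, -1)
    alleles[i] <- max(1, alleles[i] + sum(steps))
  }
  alleles
}

# net displacement of a single lineage after k ~ Poisson(rate) +/-1 steps
smm_lineage_offset <- function(rate, beta_exp) {
  if (rate <= 0) return(0L)
  k <- stats::rpois(1L, rate)
  if (k == 0) return(0L)
  sum(ifelse(stats::runif(k) < beta_exp, 1L, -1L))
}

#' Simulate a multi-population STR cohort under the stepwise mutation model
#'
#' Each locus starts from an ancestral allele pool (discretized normal).
#' Every population draws a founder pool of `founder_chromosomes` alleles
#' from the ancestral pool (with replacement — founder drift), shifts the
#' whole pool by the net of Poisson(mu x generations) +/-1 steps (mutations
#' fixed along the population's shared lineage — the source of
#' between-population divergence), and mutates each allele privately with
#' Poisson(mu x within_generations) steps; individuals then draw their two
#' alleles from the pool. At divergent loci one randomly chosen population
#' receives `divergent_extra_generations` of additional directional drift
#' (Poisson-many extra steps sharing a single random sign, emulating
#' selection-driven divergence), raising that locus's between-population
#' dosage variance and hence its Rst. Ordinary steps are +1 with
#' probability `beta_exp`, else -1, floored at 1 repeat (truncated SMM).
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (StrGenotypes), `pops` (named character
#'   vector sample -> population, labels `POP1..POPk`), and `truth` (list
#'   with per-locus `divergent` logical and the config).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_loci <- cfg$n_loci
    motifs <- vapply(sample(cfg$motif_lengths, n_loci, TRUE, cfg$motif_probs),
                     function(k) paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""),
                     "")
    pos <- sort(sample.int(2e8, n_loci))
    loci <- data.frame(
      locus_id = sprintf("STR%05d", seq_len(n_loci)),
      chrom = "chr1",
      pos_start = pos,
      pos_end = as.integer(pos + nchar(motifs) * pmax(1L, round(cfg$ancestral_mean)) - 1L),
      motif = motifs,
      ref_units = pmax(1L, round(cfg$ancestral_mean)),
      stringsAsFactors = FALSE
    )
    divergent <- stats::runif(n_loci) < cfg$divergent_frac
    pop_labels <- sprintf("POP%d", seq_len(cfg$n_populations))
    samples <- as.vector(vapply(pop_labels, function(p)
      sprintf("%s_S%03d", p, seq_len(cfg$n_per_pop)), character(cfg$n_per_pop)))
    pops <- stats::setNames(rep(pop_labels, each = cfg$n_per_pop), samples)

    n_samples <- length(samples)
    a1 <- matrix(NA_real_, n_loci, n_samples)
    a2 <- a1
    for (l in seq_len(n_loci)) {
      anc <- pmax(2, round(stats::rnorm(200, cfg$ancestral_mean, cfg$ancestral_sd)))
      div_pop <- if (divergent[l]) sample.int(cfg$n_populations, 1L) else 0L
      div_dir <- if (divergent[l]) sample(c(-1L, 1L), 1L) else 0L
      for (k in seq_len(cfg$n_populations)) {
        pool <- sample(anc, cfg$founder_chromosomes, replace = TRUE)
        off <- smm_lineage_offset(cfg$mu * cfg$generations[k], cfg$beta_exp)
        if (k == div_pop) {
          off <- off + div_dir * stats::rpois(1L, cfg$mu * cfg$divergent_extra_generations)
        }
        pool <- pmax(1L, pool + off)
        pool <- smm_mutate(pool, cfg$mu * cfg$within_generations, cfg$beta_exp)
        cols <- which(pops == pop_labels[k])
        a1[l, cols] <- sample(pool, length(cols), replace = TRUE)
        a2[l, cols] <- sample(pool, length(cols), replace = TRUE)
      }
    }
    g <- str_genotypes(loci, samples, a1, a2)
    list(genotypes = g, pops = pops,
         truth = list(divergent = stats::setNames(divergent, loci$locus_id),
                      config = cfg))
  })
}

#' Plant missing calls at random
#'
#' @param g StrGenotypes.
#' @param rate per-call missingness probability.
#' @param seed RNG seed.
#' @return StrGenotypes with calls knocked out.
#' @export
add_missingness <- function(g, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, {
    drop <- matrix(stats::runif(length(g$a1)) < rate, nrow(g$a1))
    g$a1[drop] <- NA
    g$a2[drop] <- NA
    g
  })
}

#' Simulate expression with planted cis STR effects
#'
#' For each simulated gene a TSS is placed near a randomly chosen locus;
#' causal genes get `Y = beta_true * z(dosage) + W alpha + eps` with
#' `eps ~ N(0, sigma^2)`, non-causal genes omit the dosage term. Covariates
#' are sex and two continuous ancestry axes (population means plus noise),
#' with fixed coefficients `alpha`.
#'
#' @param d DosageMatrix (samples x loci, loci table attached).
#' @param pops named population vector (for the ancestry covariates).
#' @param n_genes number of genes.
#' @param causal_frac fraction of genes with a true eSTR effect.
#' @param beta_true effect size per SD of dosage.
#' @param sigma residual SD.
#' @param window_bp TSS offset range for the causal locus.
#' @param preferred_anchors optional locus ids favoured as causal anchors
#'   (e.g. environment-responsive loci, so that dual-associated loci exist).
#' @param preferred_frac fraction of genes anchored at preferred loci when
#'   supplied.
#' @param seed RNG seed.
#' @return list: `expr` (samples x genes), `covariates` (samples x 3),
#'   `genes` (annotation: gene_id, chrom, tss, strand, start, end),
#'   `truth` (data.frame gene_id, locus_id, beta_true).
#' @export
simulate_expression <- function(d, pops, n_genes = 50, causal_frac = 0.5,
                                beta_true = 0.5, sigma = 1,
                                window_bp = 500000,
                                preferred_anchors = NULL, preferred_frac = 0.5,
                                seed = 1) {
  loci <- attr(d, "loci")
  samples <- rownames(d)
  with_seed(seed, {
    n <- length(samples)
    sex <- stats::rbinom(n, 1, 0.5)
    pop_idx <- as.integer(factor(pops[samples]))
    anc1 <- pop_idx + stats::rnorm(n, 0, 0.3)
    anc2 <- (pop_idx %% 2) + stats::rnorm(n, 0, 0.3)
    W <- cbind(sex = sex, anc1 = anc1, anc2 = anc2)
    rownames(W) <- samples
    alpha <- c(0.2, 0.3, -0.1)

    anchor <- sample(nrow(loci), n_genes, replace = TRUE)
    pref <- match(intersect(preferred_anchors, loci$locus_id), loci$locus_id)
    if (length(pref)) {
      n_pref <- min(length(pref), round(preferred_frac * n_genes))
      if (n_pref > 0) {
        anchor[seq_len(n_pref)] <- sample(pref, n_pref, replace = n_pref > length(pref))
      }
    }
    tss <- pmax(1L, loci$pos_start[anchor] +
                  as.integer(round(stats::runif(n_genes, -window_bp / 2, window_bp / 2))))
    genes <- data.frame(
      gene_id = sprintf("GENE%04d", seq_len(n_genes)),
      chrom = loci$chrom[anchor], tss = tss, strand = "+",
      start = tss, end = tss + 1000L, stringsAsFactors = FALSE
    )
    causal <- stats::runif(n_genes) < causal_frac
    expr <- matrix(NA_real_, n, n_genes, dimnames = list(samples, genes$gene_id))
    truth <- data.frame(gene_id = genes$gene_id,
                        locus_id = NA_character_,
                        beta_true = 0, stringsAsFactors = FALSE)
    for (j in seq_len(n_genes)) {
      base <- as.vector(W %*% alpha) + stats::rnorm(n, 0, sigma)
      if (causal[j]) {
        x <- d[, anchor[j]]
        z <- zscore(x)
        z[is.na(z)] <- 0
        if (isTRUE(attr(zscore(x), "zero_variance"))) {
          causal[j] <- FALSE
        } else {
          base <- base + beta_true * z
          truth$locus_id[j] <- loci$locus_id[anchor[j]]
          truth$beta_true[j] <- beta_true
        }
      }
      expr[, j] <- base
    }
    list(expr = expr, covariates = W, genes = genes, truth = truth)
  })
}

#' Simulate environment variables with population-confounded gradients
#'
#' Altitude is drawn around population means; annual mean temperature is a
#' decreasing linear function of altitude plus noise (the negative
#' correlation is built in); solar radiation increases with altitude. Loci
#' designated as true environment responders have both alleles shifted by
#' `round(env_effect * z(altitude))` per individual, which moves dosage
#' along the altitude gradient; the modified genotypes are returned.
#'
#' @param g StrGenotypes.
#' @param pops named population vector.
#' @param pop_altitude_means named numeric vector of per-population mean
#'   altitude (m); default spreads populations from lowland to plateau.
#' @param altitude_sd per-individual altitude SD (m).
#' @param effect_frac fraction of loci with a true environment effect.
#' @param env_effect shift, in repeat units per SD of altitude.
#' @param seed RNG seed.
#' @return list: `env` (data.frame sample_id, altitude_m, temp_c_annual_mean,
#'   solar_kj_m2_day), `genotypes` (shifted StrGenotypes), `truth`
#'   (named logical: locus has a planted effect).
#' @export
simulate_environment <- function(g, pops, pop_altitude_means = NULL,
                                 altitude_sd = 300, effect_frac = 0.05,
                                 env_effect = 2, seed = 1) {
  stopifnot(inherits(g, "StrGenotypes"))
  labs <- unique(pops[g$samples])
  if (is.null(pop_altitude_means)) {
    pop_altitude_means <- stats::setNames(
      seq(400, 4200, length.out = length(labs)), labs)
  }
  with_seed(seed, {
    alt <- stats::rnorm(length(g$samples),
                        pop_altitude_means[pops[g$samples]], altitude_sd)
    alt <- pmax(0, alt)
    temp <- 22 - 0.005 * alt + stats::rnorm(length(alt), 0, 1)
    solar <- 15000 + 2 * alt + stats::rnorm(length(alt), 0, 800)
    env <- data.frame(sample_id = g$samples, altitude_m = alt,
                      temp_c_annual_mean = temp, solar_kj_m2_day = solar,
                      stringsAsFactors = FALSE)
    effect <- stats::runif(nrow(g$loci)) < effect_frac
    if (any(effect)) {
      zalt <- zscore(alt)
      shift <- round(env_effect * zalt)
      for (l in which(effect)) {
        ok <- !is.na(g$a1[l, ])
        g$a1[l, ok] <- pmax(1, g$a1[l, ok] + shift[ok])
        g$a2[l, ok] <- pmax(1, g$a2[l, ok] + shift[ok])
      }
    }
    list(env = env, genotypes = g,
         truth = stats::setNames(effect, g$loci$locus_id))
  })
}

#' Simulate trios with a known transmission mutation rate
#'
#' Pairs up existing samples as parents; each child allele copies a uniformly
#' chosen allele of the corresponding parent and then mutates by one step
#' (+1 with probability `beta_exp`, floored at 1) with probability
#' `mutation_rate`. Planted mutations are recorded per trio-locus.
#'
#' @param g StrGenotypes of the parents.
#' @param n_trios number of trios (requires `2 * n_trios` distinct parents).
#' @param mutation_rate per-transmission mutation probability.
#' @param beta_exp expansion bias of mutation steps.
#' @param seed RNG seed.
#' @return list: `genotypes` (parents + children), `trios` (data.frame child,
#'   father, mother), `truth` (data.frame child, locus_id, parent, mutated).
#' @export
simulate_trios <- function(g, n_trios, mutation_rate = 0, beta_exp = 0.524,
                           seed = 1) {
  stopifnot(inherits(g, "StrGenotypes"))
  if (2 * n_trios > length(g$samples)) stop("not enough samples to form parents")
  with_seed(seed, {
    parents <- sample(g$samples, 2 * n_trios)
    fathers <- parents[seq_len(n_trios)]
    mothers <- parents[n_trios + seq_len(n_trios)]
    children <- sprintf("CHILD%03d", seq_len(n_trios))
    n_loci <- nrow(g$loci)
    ca1 <- matrix(NA_real_, n_loci, n_trios)
    ca2 <- ca1
    mut_records <- vector("list", n_trios)
    for (t in seq_len(n_trios)) {
      fi <- match(fathers[t], g$samples)
      mi <- match(mothers[t], g$samples)
      pick_f <- stats::runif(n_loci) < 0.5
      pick_m <- stats::runif(n_loci) < 0.5
      pat <- ifelse(pick_f, g$a1[, fi], g$a2[, fi])
      mat <- ifelse(pick_m, g$a1[, mi], g$a2[, mi])
      mut_p <- stats::runif(n_loci) < mutation_rate & !is.na(pat)
      mut_m <- stats::runif(n_loci) < mutation_rate & !is.na(mat)
      step <- function(x) pmax(1, x + ifelse(stats::runif(length(x)) < beta_exp, 1, -1))
      pat[mut_p] <- step(pat[mut_p])
      mat[mut_m] <- step(mat[mut_m])
      ca1[, t] <- pat
      ca2[, t] <- mat
      any_mut <- mut_p | mut_m
      mut_records[[t]] <- if (any(any_mut)) data.frame(
        child = rep(children[t], sum(any_mut)),
        locus_id = g$loci$locus_id[any_mut],
        paternal = mut_p[any_mut],
        maternal = mut_m[any_mut],
        stringsAsFactors = FALSE
      ) else NULL
    }
    both <- is.na(ca1) | is.na(ca2)
    ca1[both] <- NA; ca2[both] <- NA
    all_g <- str_genotypes(
      g$loci, c(g$samples, children),
      cbind(g$a1, ca1), cbind(g$a2, ca2)
    )
    list(genotypes = all_g,
         trios = data.frame(child = children, father = fathers,
                            mother = mothers, stringsAsFactors = FALSE),
         truth = do.call(rbind, mut_records))
  })
}

#' Inject long-allele expansions into chosen populations
#'
#' Sets one allele of randomly chosen carriers to `target_units` at each
#' requested locus, emulating rare pathogenic-range expansions.
#'
#' @param g StrGenotypes.
#' @param pops named population vector.
#' @param locus_ids loci to expand.
#' @param carrier_pop population receiving the expansions.
#' @param carrier_frac fraction of that population made carriers.
#' @param target_units repeat-unit count of the injected allele.
#' @param seed RNG seed.
#' @return list: `genotypes`, `truth` (data.frame locus_id, sample, units).
#' @export
inject_expansions <- function(g, pops, locus_ids, carrier_pop,
                              carrier_frac = 0.2, target_units = 40, seed = 1) {
  stopifnot(inherits(g, "StrGenotypes"))
  with_seed(seed, {
    pool <- g$samples[pops[g$samples] == carrier_pop]
    recs <- list()
    for (id in locus_ids) {
      l <- match(id, g$loci$locus_id)
      if (is.na(l)) stop("unknown locus: ", id)
      carriers <- sample(pool, max(1, round(carrier_frac * length(pool))))
      cols <- match(carriers, g$samples)
      g$a2[l, cols] <- target_units
      low <- !is.na(g$a1[l, cols]) & g$a1[l, cols] > target_units
      if (any(low)) g$a1[l, cols][low] <- target_units
      recs[[id]] <- data.frame(locus_id = id, sample = carriers,
                               units = target_units, stringsAsFactors = FALSE)
    }
    list(genotypes = g, truth = do.call(rbind, recs))
  })
}

#' Simulate SNP dosages in planted LD with STR loci
#'
#' For each selected STR locus a SNP is placed at a random offset within the
#' window; its 0/1/2 dosage is generated so that its correlation with the
#' STR dosage decays linearly with distance from `r_at_zero` to `r_at_window`.
#'
#' @param d DosageMatrix.
#' @param n_snps number of SNPs.
#' @param window_bp placement window around the anchor STR.
#' @param r_at_zero,r_at_window target correlations at distance 0 and at the
#'   window edge.
#' @param seed RNG seed.
#' @return list: `snp_dosage` (samples x SNPs, 0/1/2), `snp_pos` (data.frame
#'   snp_id, chrom, pos), `truth` (anchor locus and target r per SNP).
#' @export
simulate_snps <- function(d, n_snps = 100, window_bp = 200000,
                          r_at_zero = 0.9, r_at_window = 0.1, seed = 1) {
  loci <- attr(d, "loci")
  samples <- rownames(d)
  with_seed(seed, {
    anchor <- sample(nrow(loci), n_snps, replace = TRUE)
    offset <- as.integer(round(stats::runif(n_snps, -window_bp, window_bp)))
    pos <- pmax(1L, loci$pos_start[anchor] + offset)
    target_r <- r_at_zero - (r_at_zero - r_at_window) * abs(offset) / window_bp
    snp <- matrix(NA_real_, length(samples), n_snps,
                  dimnames = list(samples, sprintf("SNP%04d", seq_len(n_snps))))
    for (j in seq_len(n_snps)) {
      x <- d[, anchor[j]]
      z <- zscore(x); z[is.na(z)] <- 0
      latent <- target_r[j] * z + sqrt(max(0, 1 - target_r[j]^2)) * stats::rnorm(length(z))
      # threshold the latent gaussian into 0/1/2 at its empirical tertiles
      qs <- stats::quantile(latent, c(1 / 3, 2 / 3), names = FALSE)
      snp[, j] <- findInterval(latent, qs)
    }
    list(snp_dosage = snp,
         snp_pos = data.frame(snp_id = colnames(snp), chrom = loci$chrom[anchor],
                              pos = pos, stringsAsFactors = FALSE),
         truth = data.frame(snp_id = colnames(snp),
                            locus_id = loci$locus_id[anchor],
                            target_r = target_r, distance_bp = offset,
                            stringsAsFactors = FALSE))
  })
}
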