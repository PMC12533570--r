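#' Default end-to-end pipeline configuration
#'
#' Analysis thresholds are the field's conventions: hypervariability at
#' heterozygosity > 0.1, divergence tiers at Rst 0.1/0.2, |CPM| > 0.3,
#' alpha and FDR 0.05, eQTL window 500 kb, LD and shuffle windows 200 kb,
#' 2000 resampling replicates, 10% sampling fraction, and population
#' subsampling to 100.
#'
#' @param out_dir output directory for stage TSVs.
#' @param seed global seed; each stage derives its own child seed via
#'   [derive_seed()].
#' @param sim [sim_config()] for the synthetic cohort stage.
#' @param ... overrides for individual thresholds.
#' @return named list.
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = sim_config(seed = seed), ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed, sim = sim,
    het_floor = 0.1, min_call_rate = 0.5, hwe_p_floor = 1e-20,
    rst_divergent = 0.1, cpm_threshold = 0.3, alpha = 0.05, fdr = 0.05,
    window_eqtl = 500000, window_ld = 200000, shuffle_window = 200000,
    reps = 2000, frac = 0.10, max_n = 100,
    n_genes = 50, n_trios = 10, trio_mutation_rate = 0,
    n_snps = 60, missing_rate = 0.02,
    expansion_loci = 2, expansion_units = 45
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  ranges <- list(het_floor = c(0, 1), min_call_rate = c(0, 1), alpha = c(0, 1),
                 fdr = c(0, 1), frac = c(0, 1), cpm_threshold = c(0, Inf))
  for (k in names(ranges)) {
    if (cfg[[k]] < ranges[[k]][1] || cfg[[k]] > ranges[[k]][2]) {
      stop("config value out of range: ", k)
    }
  }
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: simulate -> locus summaries and filters -> divergence -> eQTL ->
#' environment (hSTR/aSTR) -> expansion -> regulation enrichment -> SNP-STR
#' LD. Every stage writes a TSV under `out_dir` and a provenance manifest
#' (seeds, stage row counts, input hashes) is written as JSON. Reruns with
#' the same config and seed are byte-identical.
#'
#' @param config [pipeline_config()] output.
#' @return list of in-memory stage results, invisibly; side effect: files
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  req <- c("out_dir", "seed", "sim")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config missing required key(s): ", paste(miss, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- simulate
  sim <- simulate_cohort(config$sim)
  env_sim <- simulate_environment(sim$genotypes, sim$pops,
                                  seed = derive_seed(config$seed, "environment_sim"))
  g <- env_sim$genotypes
  exp_loci <- with_seed(derive_seed(config$seed, "expansion_pick"), {
    cand <- g$loci$locus_id[nchar(g$loci$motif) >= 3]
    sample(cand, min(config$expansion_loci, length(cand)))
  })
  inj <- inject_expansions(g, sim$pops, exp_loci,
                           carrier_pop = unique(sim$pops)[1],
                           target_units = config$expansion_units,
                           seed = derive_seed(config$seed, "expansion_inject"))
  g <- inj$genotypes
  g <- add_missingness(g, config$missing_rate,
                       seed = derive_seed(config$seed, "missingness"))
  trio_sim <- simulate_trios(g, config$n_trios,
                             mutation_rate = config$trio_mutation_rate,
                             seed = derive_seed(config$seed, "trios"))
  write_genotypes(g, file.path(config$out_dir, "genotypes.tsv"))
  wtsv(data.frame(sample_id = names(sim$pops), population = unname(sim$pops)),
       "populations")
  wtsv(trio_sim$trios, "trios")

  # --- summaries and filters
  summaries <- summarize_loci(g)
  kept <- filter_loci(summaries, config$min_call_rate, config$hwe_p_floor)
  summaries$retained <- summaries$locus_id %in% kept
  wtsv(summaries, "locus_summaries")
  g_kept <- subset_genotypes(g, loci = kept)
  d <- dosage_matrix(g_kept)
  summ_kept <- summaries[summaries$retained, , drop = FALSE]

  # --- Mendelian consistency
  mi <- mendelian_consistency(trio_sim$genotypes, trio_sim$trios)
  wtsv(mi$per_trio, "mi_per_trio")

  # --- divergence
  div <- divergence_scan(g_kept, sim$pops, het_floor = config$het_floor,
                         max_n = config$max_n,
                         seed = derive_seed(config$seed, "divergence"),
                         summaries = summ_kept)
  div_calls <- divergent_loci(div, threshold = config$rst_divergent)
  wtsv(div, "divergence_records")
  wtsv(div_calls, "divergent_loci")

  # --- eQTL
  expr_sim <- simulate_expression(d, sim$pops, n_genes = config$n_genes,
                                  window_bp = config$window_eqtl,
                                  preferred_anchors = names(env_sim$truth)[env_sim$truth],
                                  seed = derive_seed(config$seed, "expression"))
  scan <- eqtl_scan(d, expr_sim$expr, expr_sim$covariates, expr_sim$genes,
                    window_bp = config$window_eqtl, het_floor = config$het_floor,
                    summaries = summ_kept)
  calls <- call_eqtl_estr(scan, alpha = config$alpha, fdr = config$fdr)
  wtsv(calls$records, "eqtl_records")
  wtsv(calls$genes, "estr_genes")

  # --- environment / hSTR / aSTR
  panel <- env_scan(d, env_sim$env, het_floor = config$het_floor,
                    summaries = summ_kept)
  cpm_tab <- combine_effects(panel)
  fish <- fisher_combine(panel)
  hstr <- call_hstr(cpm_tab, fish, cpm_threshold = config$cpm_threshold,
                    alpha = config$alpha, eqtl_calls = calls)
  corr <- cpm_rst_correlation(hstr, div)
  wtsv(env_sim$env, "environment")
  wtsv(hstr, "hstr_calls")
  wtsv(corr, "cpm_rst_correlation")

  # --- expansion
  outliers <- find_outlier_alleles(g_kept, sim$pops)
  prof <- expansion_profile(g_kept, sim$pops)
  pops_labels <- unique(sim$pops)
  ldt <- length_difference_test(g_kept, sim$pops, pops_labels[1],
                                pops_labels[length(pops_labels)])
  wtsv(outliers, "expansion_outliers")
  wtsv(as.data.frame(prof$all_scores), "expansion_scores")
  wtsv(ldt, "length_difference")

  # --- regulation: shuffle enrichment of eQTL loci in synthetic marks
  eqtl_ids <- unique(calls$eqtls$locus_id)
  enrich <- NULL
  if (length(eqtl_ids) >= 2) {
    loci_tab <- g_kept$loci
    focal <- loci_tab[loci_tab$locus_id %in% eqtl_ids, , drop = FALSE]
    ctrl <- loci_tab[!loci_tab$locus_id %in% eqtl_ids, , drop = FALSE]
    marks <- with_seed(derive_seed(config$seed, "marks"), {
      ms <- sort(sample.int(2e8, 400))
      interval_set(rep("chr1", 400), ms, ms + 5000L, "synthetic_marks")
    })
    sizes <- c(chr1 = 2.5e8)
    enrich <- shuffle_enrichment(focal, marks, ctrl, sizes,
                                 window_bp = config$shuffle_window,
                                 reps = min(config$reps, 500),
                                 seed = derive_seed(config$seed, "shuffle"))
    wtsv(data.frame(fold_change = enrich$fold_change, p = enrich$p,
                    observed = enrich$observed_count), "shuffle_enrichment")
  }

  # --- pathway differential abundance over aSTR-affected genes
  da <- NULL
  astr <- hstr[hstr$is_astr, c("locus_id", "cpm"), drop = FALSE]
  eff <- merge(calls$eqtls[, c("locus_id", "gene_id", "beta")], astr,
               by = "locus_id")
  if (nrow(eff) >= 4) {
    dirs <- gene_disturbance(eff)
    pw <- with_seed(derive_seed(config$seed, "pathway"),
                    sample(dirs$gene_id, max(2, nrow(dirs) %/% 3)))
    da <- pathway_differential_abundance(dirs, pw, reps = min(config$reps, 500),
                                         seed = derive_seed(config$seed, "da"))
    wtsv(data.frame(da = da$da, U = da$U, D = da$D, N = da$N, p = da$p),
         "pathway_da")
  }

  # --- SNP-STR LD
  snps <- simulate_snps(d, n_snps = config$n_snps,
                        window_bp = config$window_ld,
                        seed = derive_seed(config$seed, "snps"))
  ld <- snp_str_ld(snps$snp_dosage, snps$snp_pos, d, sim$pops,
                   window_bp = config$window_ld, max_n = config$max_n,
                   seed = derive_seed(config$seed, "ld"))
  decay <- ld_decay(ld)
  wtsv(ld, "ld_records")
  wtsv(decay, "ld_decay")

  # --- provenance manifest
  tsvs <- sort(list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("strpop")),
    seed = config$seed,
    stages = stats::setNames(
      lapply(tsvs, function(f) list(md5 = unname(tools::md5sum(f)))),
      basename(tsvs)
    )
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(config$out_dir, "manifest.json"))

  invisible(list(
    genotypes = g, pops = sim$pops, truth = list(
      divergent = sim$truth$divergent, env = env_sim$truth,
      eqtl = expr_sim$truth, expansions = inj$truth, trios = trio_sim$truth
    ),
    summaries = summaries, kept = kept, mi = mi,
    divergence = div, divergent = div_calls,
    eqtl = calls, hstr = hstr, cpm_rst = corr,
    expansion = list(outliers = outliers, profile = prof, length_test = ldt),
    enrichment = enrich, pathway_da = da,
    ld = list(records = ld, decay = decay)
  ))
}
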