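#!/usr/bin/env Rscript
# Stage 1: build the synthetic study cohort.
#
# Generates a 3-population STR cohort (60 individuals per population, 300
# loci) under the truncated stepwise mutation model, layers on the
# population-confounded environment gradients (shifting dosages at the
# environment-responsive loci), injects two long-allele expansions into
# population 1, plants 2% random missingness, and adds 10 mutation-free
# trios. Writes the genotype TSV, population map, trio table, environment
# table, and a truth JSON under results/cohort/.

suppressMessages(library(strpop))

seed <- 20260928
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_cohort(sim_config(n_populations = 3, n_per_pop = 60,
                                  n_loci = 300, divergent_frac = 0.1,
                                  seed = seed))
env_sim <- simulate_environment(sim$genotypes, sim$pops,
                                seed = derive_seed(seed, "environment_sim"))
g <- env_sim$genotypes

exp_candidates <- g$loci$locus_id[nchar(g$loci$motif) >= 3]
inj <- inject_expansions(g, sim$pops,
                         exp_candidates[1:2], carrier_pop = "POP1",
                         target_units = 45,
                         seed = derive_seed(seed, "expansion_inject"))
g <- add_missingness(inj$genotypes, 0.02, seed = derive_seed(seed, "missingness"))
trio_sim <- simulate_trios(g, 10, mutation_rate = 0,
                           seed = derive_seed(seed, "trios"))

write_genotypes(g, file.path(out, "genotypes.tsv"))
write_genotypes(trio_sim$genotypes, file.path(out, "genotypes_with_trios.tsv"))
write.table(data.frame(sample_id = names(sim$pops), population = unname(sim$pops)),
            file.path(out, "populations.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(trio_sim$trios, file.path(out, "trios.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(env_sim$env, file.path(out, "environment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(divergent = names(which(sim$truth$divergent)),
       env_effect = names(which(env_sim$truth)),
       expansions = inj$truth, seed = seed),
  file.path(out, "truth.json"), auto_unbox = TRUE
)

cat("Cohort:", nrow(g$loci), "loci x", length(g$samples), "samples;",
    sum(sim$truth$divergent), "divergent and", sum(env_sim$truth),
    "environment-responsive loci planted;",
    nrow(inj$truth), "expansion carriers injected.\n")
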