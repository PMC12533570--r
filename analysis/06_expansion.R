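#!/usr/bin/env Rscript
# Stage 6: repeat expansion and contraction analysis.
#
# Flags outlier alleles (motif >= 3 bp, |delta| >= 10 repeats and >= 50% of
# the within-population major allele), profiles expansion scores
# ((p95 - median)/median) and allele-length CVs across populations, tests
# population-pair length differences (Wilcoxon + BH), and runs the
# pathogenic-locus TRDS null at the two injected expansion loci.

suppressMessages(library(strpop))

seed <- 20260928
g <- read_genotypes("results/cohort/genotypes.tsv")
pops <- read_population_map("results/cohort/populations.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json", simplifyVector = TRUE)

outliers <- find_outlier_alleles(g, pops)
prof <- expansion_profile(g, pops, score_floor = 2)
ldt <- length_difference_test(g, pops, "POP1", "POP3")
write.table(outliers, "results/expansion_outliers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(locus_id = rownames(prof$scores), as.data.frame(prof$scores)),
            "results/expansion_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ldt, "results/length_difference.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

injected <- unique(truth$expansions$locus_id)
trds_rows <- do.call(rbind, lapply(injected, function(id) {
  cbind(locus_id = id,
        pathogenic_trds_null(g, pops, id, pathogenic_threshold = 35,
                             n_control = 150, reps = 200,
                             seed = derive_seed(seed, id)))
}))
write.table(trds_rows, "results/pathogenic_trds.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d outlier alleles; %d loci with expansion score >= 2; %d length outliers (q < 0.05).\n",
            nrow(outliers), nrow(prof$scores), sum(ldt$outlier)))
cat(sprintf("Injected loci detected as outlier alleles: %d/%d; TRDS-flagged populations: %s.\n",
            sum(injected %in% outliers$locus_id), length(injected),
            paste(unique(trds_rows$population[trds_rows$flagged]), collapse = ", ")))
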