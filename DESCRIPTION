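Package: strpop
Title: Population Genetics and Functional Association Analysis of Short Tandem Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-genotyping analysis of short tandem repeat (STR) cohorts:
    per-locus summaries and quality filters, Mendelian-inheritance checks over
    trios, population divergence via the dosage-variance fixation index (Rst)
    and the 2-Wasserstein tandem repeat disparity score (TRDS), dosage-based
    expression QTL mapping with gene-level FDR, environment association with
    empirical-Bayes combined effects and hSTR/aSTR calling, repeat expansion
    scoring and outlier detection, window-shuffle and resampling enrichment
    nulls, pathway differential abundance, and SNP-STR linkage disequilibrium.
    Includes a synthetic-cohort generator (stepwise mutation model with
    population drift, planted eQTL and environment effects, trios, and
    injected expansions) that emits ground truth for calibration tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
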