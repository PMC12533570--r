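---
title: "Population and functional analysis of short tandem repeats with strpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population and functional analysis of short tandem repeats with strpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpop)
```

## Scope and data model

`strpop` analyses short tandem repeat (STR) genotypes *after* calling:
every individual carries two alleles per locus, each recorded as a
repeat-unit count. The central container (`str_genotypes()`) stores an
ordered locus table plus two loci-by-samples allele matrices; pairs are
unordered (stored sorted) and phase is never represented. Mononucleotide
repeats are excluded at the reader boundary (motif length must be 2-6 bp),
and a call missing either allele is treated as fully missing — genotype
callers rarely emit trustworthy half-calls, and no downstream statistic
here can use a lone allele.

The *dosage* of an individual at a locus is the sum of its two allele
repeat counts. Dosage is the workhorse quantity: population divergence,
eQTL mapping, environment association and LD all operate on it.

## Locus summaries, filters, and trio checks

Per locus we report the call rate, allele spectrum, expected
heterozygosity $1 - \sum_i p_i^2$, Shannon entropy ($-\sum_i p_i \log_2
p_i$, in bits), the major allele (frequency ties broken toward the shorter
allele so outputs are deterministic), a polymorphism class (pSTR when at
least two alleles are observed, mSTR otherwise) and a hypervariability
flag (heterozygosity above 0.1). Only hypervariable loci enter the
divergence, eQTL and environment scans: below that level there is too
little dosage variance to drive any association.

Retention follows the standard post-calling rules: call rate at least 0.5
and Hardy-Weinberg equilibrium p at least $10^{-20}$. Because STRs are
multiallelic, HWE is tested on the biallelic collapse (major allele versus
all others pooled) with the exact conditional test. Collapsing is the
simplest defensible treatment — the test exists to catch gross genotyping
artifacts (e.g. systematic heterozygote deficits from allelic dropout),
and those distort the collapsed table as clearly as the full one.

Trio consistency follows the Mendelian-inheritance rule: a trio-locus
(counted only when all three members are called) is valid when the two
child alleles can be assigned one to each parent. The rate is symmetric in
the parent labels, and on mutation-free simulated trios it is exactly 1.

## Population divergence: Rst and TRDS

Rst decomposes dosage variance: with $\bar S$ the total variance of the
pooled groups and $S_w$ the sample-size-weighted mean within-population
variance,

$$R_{st} = \frac{\bar S - S_w}{\bar S}.$$

Both variances are plug-in (denominator $n$) moments, so the decomposition
is exact: $R_{st}$ equals the between-population share of total dosage
variance, is exactly 0 when the groups have identical dosage lists, and
exactly 1 when each group is fixed for a different dosage. The estimator
is therefore non-negative by construction; under label shuffling its mean
sits $O(1/N)$ above zero rather than at zero, a bias that is negligible at
the subsample sizes used (at most 100 per group, drawn without replacement
under a caller-supplied seed to keep cross-population comparisons balanced
and reproducible). $S_w$ weights populations by their subsample sizes;
weighting by $n_k - 1$ would trade exactness of the decomposition for
unbiasedness, and we prefer the exact identity because the downstream
thresholds (0.1 and 0.2 tiers) are conventions, not inferential cutoffs.
Loci with zero pooled variance are flagged undefined and excluded from
summaries.

TRDS is the 2-Wasserstein distance between two allele distributions,
computed exactly through the quantile representation
$W_2^2 = \int_0^1 (F_a^{-1}(q) - F_b^{-1}(q))^2\,dq$ evaluated
segment-by-segment on the union of the two CDFs' breakpoints. $W_2$ (not
$W_2^2$) is returned because it carries repeat-unit units and satisfies
the triangle inequality; the squared form is available via `squared =
TRUE` for variance-style aggregation.

## The synthetic cohort generator

All calibration and recovery tests run against `simulate_cohort()` and its
companions, which emit ground truth alongside the data. The generative
model is a truncated stepwise mutation model (SMM):

* each locus draws an ancestral allele pool (discretized normal, default
  mean 15 repeats, SD 3, floored at 2);
* each population samples a founder pool (default 150 chromosomes) from
  the ancestral pool — founder drift;
* mutations fixed along the population's shared lineage shift the whole
  founder pool by the net of Poisson($\mu G$) steps of $\pm 1$; this is
  the source of between-population divergence and grows with the
  configured drift generations $G$;
* private mutations (Poisson($\mu G_w$) per allele) add within-population
  heterogeneity without divergence;
* all steps are $+1$ with probability 0.524 — matching the observed slight
  excess of expansions over contractions in polymorphic STR catalogs —
  and alleles are floored at one repeat (the truncation).

Splitting drift into a shared-lineage walk and private mutations keeps the
two variance components independently tunable, which the calibration tests
rely on: estimated Rst rises monotonically with drift generations while
heterozygosity stays put. At *divergent* loci one randomly chosen
population receives extra drift whose steps share a single random sign
(directional, selection-like divergence). A symmetric random walk leaves
substantial probability of a near-zero net shift, which would make
"divergent" labels unrecoverable by construction; directional drift is
also the biologically intended reading of a selected locus.

Planted effects elsewhere: expression is $Y = \beta\,z(X) + W\alpha +
\varepsilon$ with known covariates (sex plus two ancestry axes);
environment variables are drawn around population means with temperature
falling ~5 °C per km of altitude and radiation rising with altitude, so
the environment is *confounded with population structure by design*,
exactly the regime the hSTR caller must survive; trios copy random
parental alleles with a configurable $\pm 1$ transmission mutation rate;
expansions are injected directly as long alleles in chosen carriers.

What the generator does not emulate: coalescent gene genealogies,
recombination and haplotype structure, locus-specific mutation rates,
genotyping error, and sequence-level variation (all statistics consume
repeat counts only). Passing tests therefore demonstrate estimator
correctness and calibration under a clean SMM cohort, not robustness to
caller artifacts in real data.

## eQTL mapping

For every hypervariable locus within ±500 kb of a gene's TSS we fit
ordinary least squares of expression on z-scored dosage plus covariates
over pairwise-complete samples (a rank-inverse-normal helper is provided
for raw expression). Pairs with fewer than 30 complete samples — a
stability floor we chose, exposed as `min_n` — or constant dosage are
skipped and counted. Two-stage multiplicity control mirrors standard
STR-eQTL practice: per-gene Bonferroni over the pairs *actually fitted*
for that gene (skipped pairs never tested nothing, so they do not inflate
m), pair significance at adjusted p < 0.05, then Benjamini-Hochberg across
genes on each gene's best adjusted p, with eSTR genes at q < 0.05. The
permuted-identifier control permutes expression rows against genotypes
(covariates travel with expression, so only the genotype link is broken).

The divergent-versus-background eQTL enrichment resamples 10% of each
category 2000 times and compares the two hit-proportion vectors with a
two-sided Wilcoxon test. The 2000 pseudo-replicates are not independent
samples, so the p-value is a descriptive convention rather than a
calibrated error rate; we reproduce it as the field reports it and expose
the full distributions.

## Environment association and hSTR/aSTR calling

Each variable (altitude; inverse annual mean temperature; solar radiation)
is z-scored and regressed one at a time against z-scored dosage. For
simple regression on standardized variables both orientations give the
same t statistic and p, so the standardized slope is reported. The
temperature reciprocal is taken on the Kelvin scale: a Celsius reciprocal
is singular at 0 °C, while the Kelvin form is monotone decreasing and
finite over all physical temperatures, preserving the intended alignment
(all three variables rise with altitude stress).

Per-variable effects are combined by a deliberately simple empirical-Bayes
normal-means model: between-locus effect variance per variable by method
of moments, $\hat\tau^2 = \max(0, \mathrm{var}(\hat\beta) -
\overline{se^2})$, posterior mean $\hat\beta\,\hat\tau^2 / (\hat\tau^2 +
se^2)$, and the combined posterior mean (CPM) as the unweighted mean over
variables. This is a stand-in for full multivariate adaptive shrinkage: it
preserves the two properties the pipeline uses — shrinkage toward zero
(|posterior| ≤ |estimate| always, vanishing as $se \to \infty$) and one
combined effect per locus — but learns no cross-variable covariance and no
null correlation structure. With fewer than 10 loci $\hat\tau^2$ is
meaningless and the function warns and returns unshrunk means.

hSTRs require both |CPM| > 0.3 and a BH-adjusted Fisher combined p below
0.05; aSTRs are hSTRs that are also significant eQTL loci. The CPM scale
depends on the shrinkage model, so the 0.3 threshold is configurable;
0.3 is retained as the conventional default. The |CPM|-Rst correlation is
Pearson over hSTR loci per population pair, flagged undefined when Rst is
constant.

## Expansion analysis

Outlier alleles must satisfy all three criteria: motif length ≥ 3 bp,
absolute deviation from the major allele ≥ 10 repeats, and deviation ≥ 50%
of the major allele. The major allele is computed within the analysed
population for both deviation criteria — the coherent reading when
populations are screened one at a time. The expansion score is (95th
percentile − median) / median of allele lengths within one population;
the percentile uses linear interpolation (R type 7), fixed and documented
because the score is sensitive to the interpolation rule at small samples.
Loci reaching score ≥ 2 in any population enter the cross-population CV
profile (clustering of that matrix is left to the caller). Group length
differences use the two-sided Wilcoxon rank-sum test with BH adjustment.

For pathogenic-range loci, each population's allele distribution is
compared by TRDS against a 500-sample random control; the null redraws
both a pseudo-population of the same size and a fresh control per
replicate, and a population is flagged above the null's 95th percentile.
The redraw null is what makes the flag calibrated (a random subsample is
flagged at ~5%); note that when one population carries a real shift, its
*complement* also deviates from the contaminated cohort mixture and can be
flagged — an inherent property of mixture controls, visible in the toy
workflow.

## Interval enrichment and pathway differential abundance

Interval sets are GRanges (1-based inclusive internally; BED converts from
0-based half-open at the boundary). The ±200-kb shuffle enrichment
relocates each focal locus uniformly within the window (width preserved,
clamped at chromosome bounds — wrap-around would break locality at
termini, and at ±200 kb the clamping bias is negligible), counts overlaps
with the marks, and builds the null from identically shuffled random
control draws (focal loci excluded). Both sides are shuffled, which is the
point of the design: it compares focal loci to controls under the *same*
locality-preserving randomization rather than to naked genomic background.
The unshuffled observed count is also reported for transparency. All
replicates are evaluated in one vectorized overlap query.

Pathway differential abundance: each affected gene's direction is the sign
of $\sum \beta \times \mathrm{CPM}$ over its aSTRs (summation is the
natural aggregation when several aSTRs hit one gene); DA = (U − D)/N over
the pathway's background size N; the null draws N genes from the
affected-gene universe 2000 times; the two-sided empirical p uses the
add-one rule and can never be 0.

## SNP-STR LD

LD is the squared Pearson correlation between SNP dosage (0/1/2) and STR
dosage over pairwise-complete samples, per population, subsampled to 100,
within ±200 kb (distance anchored at the STR's start coordinate — the
anchor is a convention and is recorded with each record). Pairs above
r² > 0.8 are flagged colocalized. A caveat the toy workflow makes visible:
a biallelic SNP cannot track a wide multiallelic dosage spectrum at
r² > 0.8, so strict colocalization requires near-dimorphic STRs; on the
synthetic cohort (all loci hypervariable by construction) the strict flag
rarely fires, and the tagging-enrichment demonstration uses a labelled
moderate-LD bar instead. Decay curves bin records by absolute distance per
population (subsampling happens before binning).

## Reproducibility machinery

Every stochastic operation takes a seed; `derive_seed(seed, stage)` fans a
single global seed out to decorrelated per-stage children (a Lehmer step),
so each pipeline stage is individually reproducible and two runs with the
same config are byte-identical. Seeded helpers restore the caller's RNG
state on exit.

## Problem sizes used in the shipped tests and workflow

The toy cohort is 3 populations × 60 samples × 300 loci with 50 genes —
sizes chosen so the complete workflow and test suite re-run comfortably on
a laptop while keeping every calibration check adequately powered (null
eQTL calibration uses 500 pairs at n = 400; effect recovery uses 200
replicates at the planted β = 0.5, σ = 1; resampling nulls use 500-2000
replicates). These are the package's study conditions, emitted by the
generator's defaults; headline numbers from population-scale cohorts
(hundreds of thousands of loci, thousands of genomes) are not reproducible
at these sizes and are not targets of the test suite.

## Known limitations

* The EB combiner ignores cross-variable covariance; strongly correlated
  environment variables (built into the design) make the CPM conservative
  rather than sharp.
* The biallelic HWE collapse can miss multiallelic disequilibrium patterns
  that leave the collapsed table balanced.
* Rst here is the plug-in between/total variance share; meta-analyses that
  require unbiased variance components should re-estimate from the
  per-locus records.
* The generator plants dosage-scale effects; sequence-level mechanisms
  (motif purity, interruptions) are out of scope.
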