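#' STR genotype container
#'
#' Builds the central genotype object: an ordered locus table plus two
#' loci-by-samples allele matrices holding repeat-unit counts. Allele pairs
#' are unordered and stored sorted ascending (`a1 <= a2`); a missing call has
#' NA in both matrices. Phase is never represented. Mononucleotide motifs are
#' rejected (motif length must be 2-6).
#'
#' @param loci data.frame with columns `locus_id`, `chrom`, `pos_start`,
#'   `pos_end`, `motif`, `ref_units`, and optionally `gene_context`, `gene_id`.
#' @param samples character vector of sample ids.
#' @param a1,a2 numeric matrices (loci x samples) of repeat-unit counts.
#' @return an object of class `StrGenotypes`.
#' @export
str_genotypes <- function(loci, samples, a1, a2) {
  stopifnot(is.data.frame(loci), nrow(loci) >= 1)
  req <- c("locus_id", "chrom", "pos_start", "pos_end", "motif", "ref_units")
  miss <- setdiff(req, names(loci))
  if (length(miss)) stop("loci is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus_id in loci table")
  if (any(loci$pos_end < loci$pos_start)) stop("pos_end < pos_start at some locus")
  ml <- nchar(loci$motif)
  if (any(ml < 2 | ml > 6)) stop("motif length outside [2, 6] (mononucleotide repeats are excluded)")
  if (any(grepl("[^ACGT]", loci$motif))) stop("motif contains non-ACGT characters")
  if (any(loci$ref_units < 1)) stop("ref_units must be >= 1")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(a1) == c(nrow(loci), length(samples))) || !all(dim(a1) == dim(a2))) {
    stop("allele matrices must be loci x samples and agree in dimension")
  }
  if (any(xor(is.na(a1), is.na(a2)))) {
    # half-missing single-allele calls are treated as missing
    half <- xor(is.na(a1), is.na(a2))
    a1[half] <- NA
    a2[half] <- NA
  }
  ok <- !is.na(a1)
  if (any(a1[ok] < 1) || any(a2[!is.na(a2)] < 1)) stop("allele repeat counts must be >= 1")
  swap <- ok & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(loci$locus_id, samples)
  structure(
    list(loci = as.data.frame(loci, stringsAsFactors = FALSE), samples = samples, a1 = a1, a2 = a2),
    class = "StrGenotypes"
  )
}

#' @export
print.StrGenotypes <- function(x, ...) {
  cat("StrGenotypes:", nrow(x$loci), "loci x", length(x$samples), "samples;",
      sprintf("%.1f%% calls present\n", 100 * mean(!is.na(x$a1))))
  invisible(x)
}

#' @export
dim.StrGenotypes <- function(x) c(nrow(x$loci), length(x$samples))

#' Subset an StrGenotypes object by loci and/or samples
#'
#' @param g StrGenotypes.
#' @param loci optional locus ids (or logical/integer index over loci).
#' @param samples optional sample ids (or index).
#' @return StrGenotypes restricted to the selection, order preserved as given.
#' @export
subset_genotypes <- function(g, loci = NULL, samples = NULL) {
  stopifnot(inherits(g, "StrGenotypes"))
  li <- seq_len(nrow(g$loci))
  si <- seq_along(g$samples)
  if (!is.null(loci)) {
    li <- if (is.character(loci)) match(loci, g$loci$locus_id) else li[loci]
    if (anyNA(li)) stop("unknown locus id in subset")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, g$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample id in subset")
  }
  str_genotypes(g$loci[li, , drop = FALSE], g$samples[si],
                g$a1[li, si, drop = FALSE], g$a2[li, si, drop = FALSE])
}

#' Read STR genotypes from TSV or VCF
#'
#' TSV dialect: columns `locus_id, chrom, pos_start, pos_end, motif,
#' ref_units`, then one column per sample containing `"a1/a2"` or `"."` for
#' missing. VCF dialect: one record per locus, INFO keys `MOTIF` and `RU`
#' (reference repeat units), and a genotype-level `REPCN` field holding the
#' two repeat-unit counts as `"a1,a2"` (`"."` for missing). Coordinates are
#' 1-based inclusive in both dialects.
#'
#' Mononucleotide-motif loci are dropped with a message; loci whose motif
#' contains non-ACGT characters are rejected and reported. Input locus order
#' is preserved.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"vcf"`; default guessed from the extension.
#' @return StrGenotypes.
#' @export
read_genotypes <- function(path, format = c("guess", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "guess") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

parse_allele_pairs <- function(chr_mat, sep, path) {
  bad <- !is.na(chr_mat) & chr_mat != "." & !grepl(paste0("^[0-9]+", sep, "[0-9]+$"), chr_mat)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed genotype '%s' at locus row %d, sample column %d in %s",
                 chr_mat[bad][1], idx[1], idx[2], path))
  }
  chr_mat[chr_mat == "."] <- NA
  a1 <- matrix(NA_real_, nrow(chr_mat), ncol(chr_mat))
  a2 <- a1
  ok <- !is.na(chr_mat)
  parts <- strsplit(chr_mat[ok], sep, fixed = TRUE)
  a1[ok] <- as.numeric(vapply(parts, `[`, "", 1L))
  a2[ok] <- as.numeric(vapply(parts, `[`, "", 2L))
  list(a1 = a1, a2 = a2)
}

drop_bad_motifs <- function(loci) {
  nonacgt <- grepl("[^ACGT]", loci$motif)
  if (any(nonacgt)) {
    warning("rejected ", sum(nonacgt), " locus/loci with non-ACGT motif: ",
            paste(utils::head(loci$locus_id[nonacgt], 5), collapse = ", "))
  }
  mono <- nchar(loci$motif) < 2 & !nonacgt
  if (any(mono)) {
    message("dropped ", sum(mono), " mononucleotide-motif locus/loci")
  }
  toolong <- nchar(loci$motif) > 6 & !nonacgt
  if (any(toolong)) warning("rejected ", sum(toolong), " locus/loci with motif longer than 6 bp")
  !(nonacgt | mono | toolong)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                          check.names = FALSE)
  fixed <- c("locus_id", "chrom", "pos_start", "pos_end", "motif", "ref_units")
  if (!all(fixed %in% names(df))) {
    stop("malformed TSV genotype file (missing header columns) in ", path)
  }
  sample_cols <- setdiff(names(df), fixed)
  if (!length(sample_cols)) stop("no sample columns in ", path)
  loci <- data.frame(
    locus_id = df$locus_id, chrom = df$chrom,
    pos_start = as.integer(df$pos_start), pos_end = as.integer(df$pos_end),
    motif = df$motif, ref_units = as.integer(df$ref_units),
    stringsAsFactors = FALSE
  )
  if (anyNA(loci$pos_start) || anyNA(loci$pos_end) || anyNA(loci$ref_units)) {
    stop("malformed numeric locus field in ", path)
  }
  keep <- drop_bad_motifs(loci)
  gm <- as.matrix(df[, sample_cols, drop = FALSE])
  al <- parse_allele_pairs(gm[keep, , drop = FALSE], "/", path)
  str_genotypes(loci[keep, , drop = FALSE], sample_cols, al$a1, al$a2)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  info_field <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]+"), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  loci <- data.frame(
    locus_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                      paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos_start = as.integer(fix$POS),
    pos_end = NA_integer_,
    motif = info_field("MOTIF"),
    ref_units = as.integer(info_field("RU")),
    stringsAsFactors = FALSE
  )
  end_str <- info_field("END")
  loci$pos_end <- ifelse(is.na(end_str),
                         loci$pos_start + nchar(loci$motif) * loci$ref_units - 1L,
                         as.integer(end_str))
  if (anyNA(loci$motif) || anyNA(loci$ref_units)) {
    stop("VCF records missing MOTIF/RU INFO keys in ", path)
  }
  keep <- drop_bad_motifs(loci)
  rep_cn <- vcfR::extract.gt(v, element = "REPCN")
  if (is.null(rep_cn)) stop("VCF lacks the REPCN genotype field in ", path)
  al <- parse_allele_pairs(rep_cn[keep, , drop = FALSE], ",", path)
  str_genotypes(loci[keep, , drop = FALSE], colnames(rep_cn), al$a1, al$a2)
}

#' Write STR genotypes to TSV or VCF
#'
#' Serializes the container in the dialects [read_genotypes()] accepts, so
#' `read_genotypes(write_genotypes(g, path))` round-trips exactly.
#'
#' @param g StrGenotypes.
#' @param path output path.
#' @param format `"tsv"` or `"vcf"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("guess", "tsv", "vcf")) {
  stopifnot(inherits(g, "StrGenotypes"))
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    gm <- matrix(".", nrow(g$loci), length(g$samples))
    ok <- !is.na(g$a1)
    gm[ok] <- paste0(g$a1[ok], "/", g$a2[ok])
    out <- cbind(
      g$loci[, c("locus_id", "chrom", "pos_start", "pos_end", "motif", "ref_units")],
      as.data.frame(gm, stringsAsFactors = FALSE)
    )
    names(out) <- c("locus_id", "chrom", "pos_start", "pos_end", "motif", "ref_units", g$samples)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"Repeat motif\">",
      "##INFO=<ID=RU,Number=1,Type=Integer,Description=\"Reference repeat units\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End coordinate (1-based inclusive)\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype placeholder\">",
      "##FORMAT=<ID=REPCN,Number=2,Type=Integer,Description=\"Repeat-unit counts of the two alleles\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
              g$samples), collapse = "\t")
    )
    gm <- matrix(".:.", nrow(g$loci), length(g$samples))
    ok <- !is.na(g$a1)
    gm[ok] <- paste0("0/0:", g$a1[ok], ",", g$a2[ok])
    recs <- vapply(seq_len(nrow(g$loci)), function(i) {
      paste(c(g$loci$chrom[i], g$loci$pos_start[i], g$loci$locus_id[i],
              strrep(g$loci$motif[i], g$loci$ref_units[i]), ".", ".", "PASS",
              sprintf("MOTIF=%s;RU=%d;END=%d", g$loci$motif[i],
                      g$loci$ref_units[i], g$loci$pos_end[i]),
              "GT:REPCN", gm[i, ]), collapse = "\t")
    }, "")
    writeLines(c(hdr, recs), path)
  }
  invisible(path)
}

#' Per-locus summary statistics
#'
#' Computes the allele spectrum over non-missing calls (two alleles per
#' called sample), call rate, expected heterozygosity `1 - sum(p^2)`,
#' Shannon entropy of the allele frequencies in bits, the major allele
#' (ties broken toward the shorter allele), the polymorphism class
#' (`pSTR` when at least two distinct alleles are observed, else `mSTR`),
#' the hypervariability flag (heterozygosity > 0.1), and the
#' Hardy-Weinberg exact p-value on the major-allele-vs-rest biallelic
#' collapse.
#'
#' @param g StrGenotypes.
#' @param locus_id single locus id.
#' @return a list of class `LocusSummary`; with zero called samples the
#'   statistics are NA and `call_rate` is 0.
#' @export
locus_summary <- function(g, locus_id) {
  stopifnot(inherits(g, "StrGenotypes"))
  i <- match(locus_id, g$loci$locus_id)
  if (is.na(i)) stop("locus not present: ", locus_id)
  a1 <- g$a1[i, ]; a2 <- g$a2[i, ]
  called <- !is.na(a1)
  call_rate <- mean(called)
  if (!any(called)) {
    return(structure(list(
      locus_id = locus_id, call_rate = 0, allele_freqs = numeric(0),
      n_alleles = NA_integer_, major_allele = NA_real_, major_af = NA_real_,
      heterozygosity = NA_real_, entropy = NA_real_, hwe_p = NA_real_,
      class = NA_character_, hypervariable = NA
    ), class = "LocusSummary"))
  }
  alleles <- c(a1[called], a2[called])
  tab <- table(alleles)
  units <- as.numeric(names(tab))
  p <- as.numeric(tab) / length(alleles)
  names(p) <- names(tab)
  # major allele: highest frequency, ties toward the shorter allele
  major <- units[order(-p, units)][1]
  het <- 1 - sum(p^2)
  ent <- -sum(p * log2(p))
  # HWE on biallelic collapse: major vs pooled rest
  is_major1 <- a1[called] == major
  is_major2 <- a2[called] == major
  nAA <- sum(is_major1 & is_major2)
  nAB <- sum(xor(is_major1, is_major2))
  nBB <- sum(!is_major1 & !is_major2)
  structure(list(
    locus_id = locus_id, call_rate = call_rate, allele_freqs = p,
    n_alleles = length(units), major_allele = major,
    major_af = unname(p[as.character(major)]),
    heterozygosity = het, entropy = ent,
    hwe_p = hwe_exact_test(nAA, nAB, nBB),
    class = if (length(units) >= 2) "pSTR" else "mSTR",
    hypervariable = het > 0.1
  ), class = "LocusSummary")
}

#' @export
print.LocusSummary <- function(x, ...) {
  cat(sprintf("LocusSummary %s: call_rate %.3f, %s alleles, het %.3f, entropy %.3f bits, %s%s\n",
              x$locus_id, x$call_rate,
              ifelse(is.na(x$n_alleles), "?", x$n_alleles),
              x$heterozygosity, x$entropy,
              ifelse(is.na(x$class), "uncalled", x$class),
              ifelse(isTRUE(x$hypervariable), " (hypervariable)", "")))
  invisible(x)
}

#' Summaries for every locus as a data frame
#'
#' @param g StrGenotypes.
#' @return data.frame with one row per locus (allele spectra omitted).
#' @export
summarize_loci <- function(g) {
  rows <- lapply(g$loci$locus_id, function(id) {
    s <- locus_summary(g, id)
    data.frame(locus_id = s$locus_id, call_rate = s$call_rate,
               n_alleles = s$n_alleles, major_allele = s$major_allele,
               major_af = s$major_af, heterozygosity = s$heterozygosity,
               entropy = s$entropy, hwe_p = s$hwe_p,
               class = ifelse(is.na(s$class), NA_character_, s$class),
               hypervariable = s$hypervariable, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hardy-Weinberg exact test for a biallelic marker
#'
#' Exact conditional test (Wigginton-Cutler-Abecasis): the p-value is the
#' total probability, conditional on the allele counts, of heterozygote
#' counts no more probable than the observed one.
#'
#' @param nAA,nAB,nBB genotype counts.
#' @return p-value in (0, 1]; monomorphic input gives 1.
#' @export
hwe_exact_test <- function(nAA, nAB, nBB) {
  stopifnot(nAA >= 0, nAB >= 0, nBB >= 0)
  n <- nAA + nAB + nBB
  if (n == 0) return(NA_real_)
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  if (nA == 0 || nB == 0) return(1)
  rare <- min(nA, nB)
  # feasible heterozygote counts share parity with `rare`
  het_vals <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(het_vals, function(h) {
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- match(nAB, het_vals)
  if (is.na(obs)) stop("internal: observed heterozygote count infeasible")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Filter loci on call rate and Hardy-Weinberg equilibrium
#'
#' Retains loci with `call_rate >= min_call_rate` and biallelic-collapse HWE
#' exact p `>= hwe_p_floor`. Uncalled loci (call rate 0) are always dropped.
#'
#' @param summaries data.frame from [summarize_loci()].
#' @param min_call_rate minimum fraction of called samples (default 0.5).
#' @param hwe_p_floor minimum HWE p-value (default 1e-20).
#' @return character vector of retained locus ids.
#' @export
filter_loci <- function(summaries, min_call_rate = 0.5, hwe_p_floor = 1e-20) {
  if (!is.numeric(min_call_rate) || min_call_rate < 0 || min_call_rate > 1) {
    stop("min_call_rate must be in [0, 1]")
  }
  keep <- summaries$call_rate >= min_call_rate &
    !is.na(summaries$hwe_p) & summaries$hwe_p >= hwe_p_floor
  summaries$locus_id[keep]
}

#' Dosage matrix (summed repeat units of the two alleles)
#'
#' @param g StrGenotypes.
#' @return samples x loci numeric matrix of class `DosageMatrix` with the
#'   locus table attached as attribute `"loci"`; missing calls stay NA.
#' @export
dosage_matrix <- function(g) {
  stopifnot(inherits(g, "StrGenotypes"))
  d <- t(g$a1 + g$a2)
  structure(d, loci = g$loci, class = c("DosageMatrix", class(d)))
}

#' Mendelian-inheritance consistency over trios
#'
#' A trio-locus is evaluated only when all three members are called; it is
#' consistent when the two child alleles can be assigned one to each parent
#' (one matches a paternal allele and the other a maternal allele).
#'
#' @param g StrGenotypes.
#' @param trios data.frame with columns `child`, `father`, `mother`.
#' @return list with `per_trio` (data.frame: child, n_evaluated, n_valid,
#'   rate), `per_locus` (data.frame: locus_id, n_evaluated, n_valid, rate)
#'   and `rate`, the overall consistency over all evaluated trio-loci.
#'   Trios with members absent from `g` are skipped with a warning.
#' @export
mendelian_consistency <- function(g, trios) {
  stopifnot(inherits(g, "StrGenotypes"),
            all(c("child", "father", "mother") %in% names(trios)))
  present <- trios$child %in% g$samples & trios$father %in% g$samples &
    trios$mother %in% g$samples
  if (any(!present)) {
    warning("skipping ", sum(!present), " trio(s) with members absent from the genotypes")
    trios <- trios[present, , drop = FALSE]
  }
  if (any(trios$child == trios$father | trios$child == trios$mother)) {
    stop("a sample appears as its own parent")
  }
  n_loci <- nrow(g$loci)
  locus_eval <- integer(n_loci); locus_valid <- integer(n_loci)
  per_trio <- data.frame(child = character(0), n_evaluated = integer(0),
                         n_valid = integer(0), rate = numeric(0))
  for (t in seq_len(nrow(trios))) {
    ci <- match(trios$child[t], g$samples)
    fi <- match(trios$father[t], g$samples)
    mi <- match(trios$mother[t], g$samples)
    c1 <- g$a1[, ci]; c2 <- g$a2[, ci]
    f1 <- g$a1[, fi]; f2 <- g$a2[, fi]
    m1 <- g$a1[, mi]; m2 <- g$a2[, mi]
    ev <- !is.na(c1) & !is.na(f1) & !is.na(m1)
    valid <- ev & (
      ((c1 == f1 | c1 == f2) & (c2 == m1 | c2 == m2)) |
      ((c2 == f1 | c2 == f2) & (c1 == m1 | c1 == m2))
    )
    locus_eval <- locus_eval + ev
    locus_valid <- locus_valid + valid
    per_trio <- rbind(per_trio, data.frame(
      child = trios$child[t], n_evaluated = sum(ev), n_valid = sum(valid),
      rate = ifelse(sum(ev) > 0, sum(valid) / sum(ev), NA_real_),
      stringsAsFactors = FALSE
    ))
  }
  per_locus <- data.frame(
    locus_id = g$loci$locus_id, n_evaluated = locus_eval, n_valid = locus_valid,
    rate = ifelse(locus_eval > 0, locus_valid / locus_eval, NA_real_),
    stringsAsFactors = FALSE
  )
  list(per_trio = per_trio, per_locus = per_locus,
       rate = if (sum(locus_eval) > 0) sum(locus_valid) / sum(locus_eval) else NA_real_)
}

#' Read a sample-to-population map
#'
#' @param path TSV with columns `sample_id`, `population` and optionally
#'   `superpopulation`.
#' @return named character vector, `names` = sample ids, values = labels,
#'   with any superpopulation as attribute.
#' @export
read_population_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "population") %in% names(df)))
  if (anyDuplicated(df$sample_id)) stop("a sample has more than one population label")
  if (any(!nzchar(df$population))) stop("empty population label")
  pops <- stats::setNames(df$population, df$sample_id)
  if ("superpopulation" %in% names(df)) {
    attr(pops, "superpopulation") <- stats::setNames(df$superpopulation, df$sample_id)
  }
  pops
}
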