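#' Build an interval set
#'
#' Intervals are held as a `GRanges` (1-based inclusive coordinates
#' internally) with a source label, giving logarithmic-time overlap queries.
#'
#' @param chrom,start,end parallel vectors (1-based inclusive).
#' @param label source label (mark name, cCRE class, ...).
#' @return a `GRanges` with metadata column `label`.
#' @export
interval_set <- function(chrom, start, end, label = "intervals") {
  if (any(end < start)) stop("interval end < start")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end)
  )
  gr$label <- label
  gr
}

#' Read a BED file into an interval set
#'
#' BED is 0-based half-open on disk; coordinates are converted to 1-based
#' inclusive at this boundary.
#'
#' @param path BED path (first three columns used).
#' @param label source label; default the file name.
#' @return GRanges.
#' @export
read_bed <- function(path, label = NULL) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least chrom, start, end: ", path)
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  interval_set(df[[1]], as.integer(df[[2]]) + 1L, as.integer(df[[3]]), label)
}

#' Write an interval set as BED (0-based half-open)
#'
#' @param gr GRanges.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count loci overlapping an interval set
#'
#' @param chrom,start,end locus coordinates (1-based inclusive).
#' @param marks GRanges.
#' @return integer: number of loci overlapping at least one interval.
#' @export
count_overlaps_loci <- function(chrom, start, end, marks) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  sum(IRanges::overlapsAny(q, marks))
}

#' Window-shuffle enrichment of loci in genomic marks
#'
#' Per replicate, each focal locus is relocated uniformly within
#' `window_bp` of its original position (width preserved, clamped to the
#' chromosome bounds) and the number of relocated loci overlapping the marks
#' is counted; the same shuffle applied to a fresh random draw of control
#' loci (same count, focal loci excluded from the pool) builds the null.
#' Fold change is the ratio of the mean shuffled-focal count to the mean
#' shuffled-control count; the empirical p is the add-one rank of the mean
#' focal count in the control-count null. The unshuffled observed focal
#' overlap count is also reported.
#'
#' @param loci data.frame with `locus_id`, `chrom`, `pos_start`, `pos_end`
#'   for the focal set.
#' @param marks GRanges.
#' @param control_pool data.frame like `loci` for the control universe
#'   (must be disjoint from the focal set).
#' @param chrom_sizes named numeric vector: chromosome -> length (bp).
#' @param window_bp shuffle window (default 200000).
#' @param reps replicates (default 2000).
#' @param seed RNG seed.
#' @return list: `fold_change`, `p`, `observed_count`, `mean_focal`,
#'   `mean_control`, `focal_counts`, `control_counts`.
#' @export
shuffle_enrichment <- function(loci, marks, control_pool, chrom_sizes,
                               window_bp = 200000, reps = 2000, seed = 1) {
  stopifnot(all(c("locus_id", "chrom", "pos_start", "pos_end") %in% names(loci)))
  if (any(loci$locus_id %in% control_pool$locus_id)) {
    stop("focal loci must be disjoint from the control pool")
  }
  if (is.null(names(chrom_sizes)) ||
      !all(unique(c(loci$chrom, control_pool$chrom)) %in% names(chrom_sizes))) {
    stop("chromosome sizes missing for some chromosomes")
  }
  n_focal <- nrow(loci)
  # all replicates are shuffled in one vectorized pass: per-locus relocations
  # for every rep are concatenated into a single overlap query, then summed
  # back per replicate
  shuffle_counts_all <- function(tab, rep_of_row) {
    w <- tab$pos_end - tab$pos_start
    lim <- chrom_sizes[tab$chrom]
    new_start <- round(tab$pos_start + stats::runif(nrow(tab), -window_bp, window_bp))
    new_start <- pmax(1, pmin(new_start, lim - w))
    q <- GenomicRanges::GRanges(tab$chrom,
                                IRanges::IRanges(new_start, new_start + w))
    hit <- IRanges::overlapsAny(q, marks)
    as.numeric(rowsum(as.numeric(hit), rep_of_row)[, 1])
  }
  with_seed(seed, {
    focal_all <- loci[rep(seq_len(n_focal), reps), , drop = FALSE]
    focal_counts <- shuffle_counts_all(focal_all, rep(seq_len(reps), each = n_focal))
    ctrl_idx <- unlist(lapply(seq_len(reps), function(r)
      sample.int(nrow(control_pool), n_focal,
                 replace = nrow(control_pool) < n_focal)))
    control_counts <- shuffle_counts_all(control_pool[ctrl_idx, , drop = FALSE],
                                         rep(seq_len(reps), each = n_focal))
    mean_focal <- mean(focal_counts)
    mean_control <- mean(control_counts)
    list(
      fold_change = if (mean_control > 0) mean_focal / mean_control else Inf,
      p = empirical_p(control_counts, mean_focal, "greater"),
      observed_count = count_overlaps_loci(loci$chrom, loci$pos_start,
                                           loci$pos_end, marks),
      mean_focal = mean_focal, mean_control = mean_control,
      focal_counts = focal_counts, control_counts = control_counts
    )
  })
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (tab-separated: id, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  sets
}

#' Per-gene expression-disturbance direction from aSTR effects
#'
#' Each gene's disturbance is the sum over its aSTRs of `beta * CPM`
#' (expression effect times combined environment effect); the gene direction
#' is the sign of that sum.
#'
#' @param astr_effects data.frame: `locus_id`, `gene_id`, `beta`, `cpm`.
#' @return data.frame: gene_id, disturbance, direction (+1/-1/0).
#' @export
gene_disturbance <- function(astr_effects) {
  stopifnot(all(c("gene_id", "beta", "cpm") %in% names(astr_effects)))
  s <- tapply(astr_effects$beta * astr_effects$cpm, astr_effects$gene_id, sum)
  data.frame(gene_id = names(s), disturbance = as.numeric(s),
             direction = sign(as.numeric(s)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pathway differential abundance with a permutation null
#'
#' Differential abundance of a pathway is `(U - D) / N`, where U and D are
#' the numbers of putatively up- and down-regulated affected genes inside the
#' pathway and N is the pathway's background size. The null draws N genes at
#' random from the full affected-gene universe per replicate and recomputes
#' the statistic; the two-sided empirical p uses the add-one rule and never
#' returns 0.
#'
#' @param gene_dirs [gene_disturbance()] output for all affected genes (the
#'   universe).
#' @param pathway_genes character vector of pathway member gene ids.
#' @param background_n pathway background size N (default: number of pathway
#'   genes supplied); must be >= 1.
#' @param reps null replicates (default 2000).
#' @param seed RNG seed.
#' @return list: `da`, `U`, `D`, `N`, `p`, `null` (length-`reps` vector).
#' @export
pathway_differential_abundance <- function(gene_dirs, pathway_genes,
                                           background_n = length(pathway_genes),
                                           reps = 2000, seed = 1) {
  if (background_n < 1) stop("pathway background size N must be >= 1")
  dirs <- stats::setNames(gene_dirs$direction, gene_dirs$gene_id)
  in_path <- dirs[names(dirs) %in% pathway_genes]
  U <- sum(in_path > 0); D <- sum(in_path < 0)
  if (background_n < length(in_path)) {
    stop("N must be at least the number of affected genes in the pathway")
  }
  da <- (U - D) / background_n
  n_draw <- min(background_n, length(dirs))
  with_seed(seed, {
    null <- vapply(seq_len(reps), function(r) {
      dd <- dirs[sample(length(dirs), n_draw)]
      (sum(dd > 0) - sum(dd < 0)) / background_n
    }, 0)
    list(da = da, U = U, D = D, N = background_n,
         p = empirical_p(null, da, "two.sided"), null = null)
  })
}
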