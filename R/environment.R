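#' Per-variable environment association scan
#'
#' For each hypervariable locus and each environmental variable (altitude,
#' inverse annual mean temperature, solar radiation), fits a simple linear
#' regression of the z-score-normalized dosage on the z-score-normalized
#' variable and records the standardized slope, its standard error and
#' two-sided p-value. For simple regression on z-scored variables the two
#' orientations give the same t statistic and p; the standardized slope is
#' reported. Temperature enters as the reciprocal of the annual mean on the
#' Kelvin scale (monotone decreasing in temperature, defined for all
#' physical values), so all three variables increase with altitude stress.
#'
#' @param d DosageMatrix.
#' @param env data.frame: `sample_id`, `altitude_m`, `temp_c_annual_mean`,
#'   `solar_kj_m2_day` (additional numeric columns are scanned too).
#' @param het_floor hypervariability gate on the dosage spectrum.
#' @param summaries optional locus summaries carrying `heterozygosity`.
#' @return data.frame of class `env_panel`: locus_id, variable, beta, se, p.
#' @export
env_scan <- function(d, env, het_floor = 0.1, summaries = NULL) {
  loci <- attr(d, "loci")
  stopifnot("sample_id" %in% names(env))
  vars <- env_variables(env)
  samples <- intersect(rownames(d), env$sample_id)
  if (!length(samples)) stop("no overlap between dosage samples and environment table")
  env <- env[match(samples, env$sample_id), , drop = FALSE]
  d <- d[samples, , drop = FALSE]
  het <- if (!is.null(summaries)) {
    stats::setNames(summaries$heterozygosity, summaries$locus_id)[loci$locus_id]
  } else {
    apply(d, 2, dosage_heterozygosity)
  }
  hyper <- which(!is.na(het) & het > het_floor)
  zv <- vars
  for (vn in names(vars)) {
    z <- zscore(vars[[vn]])
    if (isTRUE(attr(z, "zero_variance"))) {
      stop("constant environment variable: ", vn)
    }
    zv[[vn]] <- z
  }
  out <- list()
  for (li in hyper) {
    x <- d[, li]
    for (vn in names(zv)) {
      ok <- !is.na(x) & !is.na(zv[[vn]])
      if (sum(ok) < 3) next
      zx <- zscore(x[ok])
      if (isTRUE(attr(zx, "zero_variance"))) next
      co <- ols_coef(zx, cbind(v = zscore(zv[[vn]][ok])), coef_idx = 1L)
      out[[length(out) + 1L]] <- data.frame(
        locus_id = loci$locus_id[li], variable = vn,
        beta = co[["beta"]], se = co[["se"]], p = co[["p"]],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(0), variable = character(0),
               beta = numeric(0), se = numeric(0), p = numeric(0))
  class(res) <- c("env_panel", class(res))
  res
}

# extract the environment variables to scan; temperature becomes the Kelvin
# reciprocal so that all variables rise with altitude stress
env_variables <- function(env) {
  vars <- list()
  if ("altitude_m" %in% names(env)) vars$altitude <- env$altitude_m
  if ("temp_c_annual_mean" %in% names(env)) {
    vars$inv_temp <- 1 / (env$temp_c_annual_mean + 273.15)
  }
  if ("solar_kj_m2_day" %in% names(env)) vars$solar <- env$solar_kj_m2_day
  extra <- setdiff(names(env), c("sample_id", "altitude_m", "temp_c_annual_mean",
                                 "solar_kj_m2_day"))
  for (e in extra) if (is.numeric(env[[e]])) vars[[e]] <- env[[e]]
  if (!length(vars)) stop("no numeric environment variables found")
  vars
}

#' Combined posterior mean via empirical-Bayes normal-means shrinkage
#'
#' Per variable, the between-locus effect variance is estimated by method of
#' moments, `tau2 = max(0, var(beta) - mean(se^2))`, and each effect is
#' shrunk to its posterior mean `beta * tau2 / (tau2 + se^2)`. The combined
#' posterior mean (CPM) of a locus is the unweighted mean of its per-variable
#' posterior means. This is a deliberately simple stand-in for multivariate
#' adaptive shrinkage: it preserves shrinkage toward zero and yields one
#' combined effect per locus, but learns no cross-variable covariance.
#'
#' @param panel [env_scan()] output (long format: locus_id, variable, beta, se).
#' @return data.frame: locus_id, cpm, plus one `pm_<variable>` column per
#'   variable; attribute `"tau2"` carries the per-variable estimates. With
#'   fewer than 10 loci a warning is issued and raw means are returned.
#' @export
combine_effects <- function(panel) {
  stopifnot(all(c("locus_id", "variable", "beta", "se") %in% names(panel)))
  loci <- unique(panel$locus_id)
  vars <- unique(panel$variable)
  shrunk <- matrix(NA_real_, length(loci), length(vars),
                   dimnames = list(loci, vars))
  tau2 <- stats::setNames(numeric(length(vars)), vars)
  few <- length(loci) < 10
  if (few) {
    warning("fewer than 10 loci: tau2 unreliable, returning unshrunk means")
  }
  for (v in vars) {
    rows <- panel[panel$variable == v, , drop = FALSE]
    if (few) {
      shrunk[rows$locus_id, v] <- rows$beta
      tau2[v] <- NA_real_
    } else {
      t2 <- max(0, stats::var(rows$beta) - mean(rows$se^2))
      tau2[v] <- t2
      shrunk[rows$locus_id, v] <- rows$beta * t2 / (t2 + rows$se^2)
    }
  }
  out <- data.frame(locus_id = loci, cpm = rowMeans(shrunk, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  for (v in vars) out[[paste0("pm_", v)]] <- shrunk[, v]
  attr(out, "tau2") <- tau2
  out
}

#' Fisher combination of per-variable p-values, BH-adjusted across loci
#'
#' `chi2 = -2 sum(log p_i)` on `2k` degrees of freedom per locus, with the
#' survival-function p-value; the combined p-values are Benjamini-Hochberg
#' adjusted across loci.
#'
#' @param panel [env_scan()] output, or a data.frame with `locus_id` and `p`.
#' @return data.frame: locus_id, k, chi2, fisher_p, fisher_p_bh.
#' @export
fisher_combine <- function(panel) {
  stopifnot(all(c("locus_id", "p") %in% names(panel)))
  sp <- split(panel$p, panel$locus_id)
  ids <- names(sp)
  k <- vapply(sp, length, 0L)
  chi2 <- vapply(sp, function(p) -2 * sum(log(p)), 0)
  fp <- stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE)
  out <- data.frame(locus_id = ids, k = k, chi2 = chi2, fisher_p = fp,
                    fisher_p_bh = stats::p.adjust(fp, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[match(unique(panel$locus_id), out$locus_id), , drop = FALSE]
}

#' Call hSTRs (and aSTRs given an eQTL call set)
#'
#' An hSTR satisfies both `|CPM| > cpm_threshold` and BH-adjusted Fisher
#' combined p `< alpha`. An aSTR is an hSTR that is also a significant eQTL
#' locus (dual association with the high-altitude environment and with gene
#' expression).
#'
#' @param cpm_table [combine_effects()] output.
#' @param fisher_table [fisher_combine()] output.
#' @param cpm_threshold default 0.3.
#' @param alpha default 0.05.
#' @param eqtl_calls optional [call_eqtl_estr()] output for aSTR calling.
#' @return data.frame: locus_id, cpm, fisher_p_bh, is_hstr (and is_astr when
#'   `eqtl_calls` is supplied).
#' @export
call_hstr <- function(cpm_table, fisher_table, cpm_threshold = 0.3,
                      alpha = 0.05, eqtl_calls = NULL) {
  m <- merge(cpm_table[, c("locus_id", "cpm")],
             fisher_table[, c("locus_id", "fisher_p", "fisher_p_bh")],
             by = "locus_id", sort = FALSE)
  m$is_hstr <- abs(m$cpm) > cpm_threshold & m$fisher_p_bh < alpha
  if (!is.null(eqtl_calls)) {
    eqtl_loci <- unique(eqtl_calls$eqtls$locus_id)
    m$is_astr <- m$is_hstr & m$locus_id %in% eqtl_loci
  }
  m
}

#' Correlation between |CPM| and Rst over hSTR loci
#'
#' Pearson correlation between the absolute combined posterior mean and the
#' locus Rst, per population pair, restricted to hSTR loci.
#'
#' @param hstr_table [call_hstr()] output.
#' @param records [divergence_scan()] output.
#' @return data.frame: pop_a, pop_b, n, r, p; pairs whose Rst is constant are
#'   flagged with `undefined = TRUE` and NA statistics.
#' @export
cpm_rst_correlation <- function(hstr_table, records) {
  hs <- hstr_table[hstr_table$is_hstr, c("locus_id", "cpm")]
  pairs <- unique(records[, c("pop_a", "pop_b")])
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    rec <- records[records$pop_a == pairs$pop_a[i] &
                     records$pop_b == pairs$pop_b[i] &
                     !records$undefined, c("locus_id", "rst")]
    m <- merge(hs, rec, by = "locus_id")
    if (nrow(m) >= 3 && stats::sd(m$rst) > 0 && stats::sd(abs(m$cpm)) > 0) {
      ct <- stats::cor.test(abs(m$cpm), m$rst)
      out[[i]] <- data.frame(pop_a = pairs$pop_a[i], pop_b = pairs$pop_b[i],
                             n = nrow(m), r = unname(ct$estimate),
                             p = ct$p.value, undefined = FALSE,
                             stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(pop_a = pairs$pop_a[i], pop_b = pairs$pop_b[i],
                             n = nrow(m), r = NA_real_, p = NA_real_,
                             undefined = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
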