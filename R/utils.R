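#' Run code with a local, restorable RNG state
#'
#' Sets the RNG to a given seed, evaluates `expr`, and restores the previous
#' global RNG state afterwards, so seeded package internals never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific child seed from a global seed
#'
#' Deterministic fan-out so that pipeline stages are individually
#' reproducible: `child = (seed * 48271 + index) mod (2^31 - 1)`, the
#' Lehmer/Park-Miller step, which decorrelates nearby global seeds.
#'
#' @param seed global integer seed.
#' @param stage stage name (character) or index (integer).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  idx <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.numeric(stage)
  }
  m <- 2147483647
  val <- (as.numeric(seed) %% m) * 48271 + idx
  as.integer(val %% m + 1)
}

#' Z-score normalize a numeric vector
#'
#' @param x numeric vector; NAs preserved.
#' @return `(x - mean) / sd` over non-missing values; all-constant input
#'   returns zeros (with a zero-variance attribute).
#' @export
zscore <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    out <- ifelse(is.na(x), NA_real_, 0)
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  (x - mu) / s
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles via `qnorm((rank - 0.5) / n)`, the
#' transform used to normalize expression values before association testing.
#' Ties receive their average rank. NAs are preserved.
#'
#' @param x numeric vector.
#' @return transformed vector, same length.
#' @export
rank_inverse_normal <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  if (n > 0) out[ok] <- stats::qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  out
}

# internal: simple OLS of y on cbind(1, X); returns beta, se, p for column `coef_idx`
# of X (1-based among X's columns). Pairwise-complete rows must be handled by caller.
ols_coef <- function(y, X, coef_idx = 1L) {
  Xm <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xm, y)
  df <- length(y) - fit$rank
  if (df <= 0) return(c(beta = NA_real_, se = NA_real_, p = NA_real_))
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  # map requested coefficient through any pivoting
  want <- coef_idx + 1L
  pos <- match(want, fit$qr$pivot[seq_len(fit$rank)])
  if (is.na(pos)) return(c(beta = NA_real_, se = NA_real_, p = NA_real_))
  beta <- fit$coefficients[want]
  se <- sqrt(sigma2 * XtXinv[pos, pos])
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  c(beta = unname(beta), se = unname(se), p = unname(p))
}

# internal: empirical p with add-one correction, never 0
empirical_p <- function(null_values, observed, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  r <- length(null_values)
  up <- (1 + sum(null_values >= observed)) / (r + 1)
  lo <- (1 + sum(null_values <= observed)) / (r + 1)
  switch(alternative,
    greater = up,
    less = lo,
    two.sided = min(1, 2 * min(up, lo))
  )
}
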