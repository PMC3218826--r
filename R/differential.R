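# Abundance filtering, fold-change estimation, and empirical-Bayes
# moderated-t differential expression on log2 normalized miRNA counts.
#
# The moderated t shrinks each feature's residual variance toward a prior
# estimated across all features by matching the moments of log(s^2) to a
# scaled-F (log chi-square) distribution, via digamma/trigamma inversion —
# the classical empirical-Bayes linear-model approach for small replicate
# numbers.

#' Abundance filter (counts per million)
#'
#' A miRNA is retained for differential testing when its condition-mean
#' normalized count reaches `min_cpm` in at least one experimental
#' condition. The default of 300 counts per million is equivalent to a
#' relative abundance of 0.03% under normalization to 10^6 miRNA reads.
#'
#' @param counts A normalized `count_matrix`.
#' @param min_cpm Threshold in reads per million miRNA reads.
#' @return Named logical vector (one per feature).
#' @export
abundance_filter <- function(counts, min_cpm = 300) {
  stopifnot(inherits(counts, "count_matrix"), !is.null(counts$norm))
  cond <- counts$samples$condition[match(colnames(counts$norm),
                                         counts$samples$sample)]
  cm <- sapply(unique(cond), function(cc)
    rowMeans(counts$norm[, cond == cc, drop = FALSE], na.rm = TRUE))
  if (is.null(dim(cm))) cm <- matrix(cm, ncol = 1L)
  res <- apply(cm >= min_cpm, 1L, any, na.rm = TRUE)
  stats::setNames(res, rownames(counts$norm))
}

## log2(norm + pc), technical replicates (directions) averaged per
## biological replicate; returns matrix + unit metadata
.log_units <- function(counts, pseudocount = 0.5) {
  stopifnot(inherits(counts, "count_matrix"), !is.null(counts$norm))
  sm <- counts$samples
  if (is.null(sm$replicate)) sm$replicate <- 1L
  lx <- log2(counts$norm[, sm$sample, drop = FALSE] + pseudocount)
  unit <- paste(sm$condition, sm$replicate, sep = ".")
  uu <- unique(unit)
  m <- sapply(uu, function(u) rowMeans(lx[, unit == u, drop = FALSE]))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(rownames(lx), uu))
  list(expr = m,
       condition = sm$condition[match(uu, unit)],
       unit = uu)
}

#' Mean log2 fold change with replicate-pair standard errors
#'
#' Per-feature log2 fold change for a contrast, computed by pairing
#' biological replicates (replicate i of the first condition against
#' replicate i of the second), averaging the per-pair log ratios, and
#' reporting the standard error across pairs. Technical replicates
#' (opposite sequencing directions) are first averaged on the log scale
#' within each biological replicate.
#'
#' @param counts A normalized `count_matrix`.
#' @param contrast Character vector `c(cond_a, cond_b)`: fold change of a
#'   over b.
#' @param pseudocount Added to normalized counts before log2 (default 0.5,
#'   so condition-specific miRNAs with zero baseline reads stay finite).
#' @return Data frame: `feature`, `log2fc`, `se`.
#' @export
log2fc_table <- function(counts, contrast, pseudocount = 0.5) {
  lu <- .log_units(counts, pseudocount)
  a <- which(lu$condition == contrast[1L])
  b <- which(lu$condition == contrast[2L])
  if (!length(a) || !length(b))
    stop("contrast condition(s) absent from the sample sheet")
  np <- min(length(a), length(b))
  d <- lu$expr[, a[seq_len(np)], drop = FALSE] -
    lu$expr[, b[seq_len(np)], drop = FALSE]
  lfc <- rowMeans(d)
  se <- if (np > 1L) apply(d, 1L, stats::sd) / sqrt(np) else rep(NA_real_, nrow(d))
  data.frame(feature = rownames(lu$expr), log2fc = lfc, se = se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Invert the trigamma function
#'
#' Newton solve of `trigamma(x) = y`, used when matching moments of
#' log variances to estimate the prior degrees of freedom.
#'
#' @param y Positive numeric vector.
#' @return `x` with `trigamma(x) = y` (Inf maps to 0, values below
#'   `trigamma(1e7)` map to `1/y` — the asymptotic regime).
#' @keywords internal
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(NA_real_)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, 0)
}

#' Estimate the variance prior (d0, s0^2) across features
#'
#' Fits a scaled F-distribution to the observed residual variances by
#' matching the mean and variance of `log(s^2)` (digamma/trigamma moment
#' equations). When the observed spread of log variances is no larger than
#' expected from chi-square sampling alone, the prior degrees of freedom
#' are infinite and all variances shrink to the common (mean) value.
#'
#' @param s2 Per-feature residual variances (zeros are excluded from
#'   estimation).
#' @param df Residual degrees of freedom (scalar).
#' @return List with `df_prior` (d0, possibly `Inf`) and `var_prior`
#'   (s0^2).
#' @export
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("all residual variances are zero; cannot estimate a prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond chi-square sampling: infinite prior df,
    # and the pooled (mean) variance is the common value
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(df_prior = d0, var_prior = s02)
}

#' Empirical-Bayes moderated-t differential expression
#'
#' Fits, per feature, a one-way linear model of `log2(normalized + pc)` on
#' condition (technical replicates averaged into biological replicates
#' first), shrinks the residual variances toward the cross-feature prior,
#' and tests a two-condition contrast with the moderated t-statistic on
#' `d0 + d` degrees of freedom. Raw two-sided P-values are reported with
#' Benjamini-Hochberg adjusted values alongside.
#'
#' @param counts A normalized `count_matrix`.
#' @param contrast Character vector `c(cond_a, cond_b)`.
#' @param pseudocount Added before log2 (default 0.5).
#' @param min_cpm Abundance filter threshold; the filter flag is reported
#'   for every feature, and the variance prior is estimated on (and P
#'   values reported for) all features.
#' @return Data frame of class `diff_exp_table`: `feature`, `log2fc`,
#'   `se`, `s2` (residual variance), `s2_post` (moderated variance), `t`
#'   (moderated t), `df_total`, `p_value`, `adj_p_value` (BH),
#'   `passes_filter`, `max_norm` (maximal normalized count across
#'   samples). Attributes `df_prior`, `var_prior`, `df_residual` carry the
#'   prior fit.
#' @export
fit_moderated_t <- function(counts, contrast, pseudocount = 0.5,
                            min_cpm = 300) {
  lu <- .log_units(counts, pseudocount)
  groups <- factor(lu$condition)
  if (nlevels(groups) < 2L) stop("need at least two conditions")
  if (!all(contrast %in% levels(groups)))
    stop("contrast condition(s) absent: ", paste(contrast, collapse = ", "))
  X <- lu$expr
  nunits <- ncol(X)
  d <- nunits - nlevels(groups)
  if (d < 1L)
    stop("no residual degrees of freedom: need replication within conditions")
  means <- sapply(levels(groups), function(g)
    rowMeans(X[, groups == g, drop = FALSE]))
  if (is.null(dim(means)))
    means <- matrix(means, nrow = 1L,
                    dimnames = list(rownames(X), levels(groups)))
  fitted <- means[, as.character(groups), drop = FALSE]
  s2 <- rowSums((X - fitted)^2) / d
  prior <- fit_variance_prior(s2, d)
  d0 <- prior$df_prior; s02 <- prior$var_prior
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  na <- sum(groups == contrast[1L]); nb <- sum(groups == contrast[2L])
  delta <- means[, contrast[1L]] - means[, contrast[2L]]
  tstat <- delta / sqrt(s2_post * (1 / na + 1 / nb))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  lfc <- log2fc_table(counts, contrast, pseudocount)
  passes <- abundance_filter(counts, min_cpm)
  out <- data.frame(feature = rownames(X),
                    log2fc = delta,
                    se = lfc$se[match(rownames(X), lfc$feature)],
                    s2 = s2, s2_post = s2_post, t = tstat,
                    df_total = rep(df_total, length(s2)),
                    p_value = p,
                    adj_p_value = stats::p.adjust(p, method = "BH"),
                    passes_filter = passes[rownames(X)],
                    max_norm = apply(counts$norm[rownames(X), , drop = FALSE],
                                     1L, max, na.rm = TRUE),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s02
  attr(out, "df_residual") <- d
  class(out) <- c("diff_exp_table", "data.frame")
  out
}

#' Regulated features at a significance cutoff
#'
#' Features passing the abundance filter with raw P below `alpha`, ordered
#' by P ascending, split into up- and down-regulated by the sign of the
#' fold change. Selection uses the raw P-value (the reported criterion of
#' the analysis); BH-adjusted values remain available in the table.
#'
#' @param diff A `diff_exp_table` from [fit_moderated_t()].
#' @param alpha Significance level on the raw P-value.
#' @return List: `table` (selected rows, ordered by P), `n_up`, `n_down`.
#' @export
top_table <- function(diff, alpha = 0.05) {
  sel <- diff[diff$passes_filter & !is.na(diff$p_value) &
                diff$p_value < alpha, , drop = FALSE]
  sel <- sel[order(sel$p_value), , drop = FALSE]
  rownames(sel) <- NULL
  list(table = sel,
       n_up = sum(sel$log2fc > 0),
       n_down = sum(sel$log2fc < 0))
}
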