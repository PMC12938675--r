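# Group-level inference: Welch's t, Cohen's d, BH-FDR, Spearman label
# correlations, and the per-feature effect table.

#' Welch's two-sample t-test from summary statistics
#'
#' `t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided Student-t
#' p-value. Accepts printed summary numbers directly, so published group
#' means/SDs can be re-tested without raw data.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @return List with `t`, `df`, `p`.
#' @export
welch_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("negative SD", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) stop("both group variances are zero", call. = FALSE)
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' @rdname welch_ttest
#' @param x,y Raw per-subject samples for the two groups.
#' @export
welch_ttest_samples <- function(x, y) {
  welch_ttest(mean(x), stats::sd(x), length(x),
              mean(y), stats::sd(y), length(y))
}

#' Cohen's d with pooled standard deviation
#'
#' Classic pooled-SD d (positive when the first group's mean is larger);
#' `hedges = TRUE` applies the small-sample bias correction.
#'
#' @param x,y Samples for the two groups.
#' @param hedges Apply Hedges' g correction.
#' @return Scalar effect size.
#' @export
cohens_d <- function(x, y, hedges = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled SD", call. = FALSE)
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  d
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across the whole input family (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, order-preserving.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Spearman correlation of each feature with the group label
#'
#' The binary label is coded GD = 1, HC = 0, so positive rho means the
#' feature is elevated in the GD group. Constant features have undefined
#' rank correlation and are flagged (`NA`) and excluded from the ranking.
#'
#' @param fm A `feature_matrix`.
#' @return Tibble with `feature`, `spearman_rho`, sorted by `|rho|`
#'   descending (NA rho rows last).
#' @export
label_correlations <- function(fm) {
  y <- as.integer(fm$group == "GD")
  if (min(sum(y), sum(1 - y)) < 3) stop("need >= 3 subjects per group", call. = FALSE)
  X <- feature_values(fm)
  rho <- apply(X, 2, function(col) {
    if (stats::sd(col) == 0) return(NA_real_)
    stats::cor(col, y, method = "spearman")
  })
  out <- tibble::tibble(feature = colnames(X), spearman_rho = rho)
  out[order(-abs(out$spearman_rho), na.last = TRUE), ]
}

#' Per-feature effect screening table
#'
#' One row per feature: group means, Welch t/df/p on the raw per-subject
#' values, BH-FDR adjusted p across all features jointly, Cohen's d signed
#' GD - HC, and the Spearman label correlation; sorted by `|d|`
#' descending.
#'
#' @param fm A `feature_matrix` with both GD and HC subjects.
#' @return Tibble of `group_stats_row`s.
#' @export
effect_table <- function(fm) {
  gd <- fm$group == "GD"
  X <- feature_values(fm)
  y <- as.integer(gd)
  rows <- lapply(colnames(X), function(f) {
    x1 <- X[gd, f]; x2 <- X[!gd, f]
    wt <- welch_ttest_samples(x1, x2)
    tibble::tibble(
      feature = f, mean_GD = mean(x1), mean_HC = mean(x2),
      welch_t = wt$t, welch_df = wt$df, p = wt$p,
      cohens_d = cohens_d(x1, x2),
      spearman_rho = if (stats::sd(X[, f]) == 0) NA_real_ else
        stats::cor(X[, f], y, method = "spearman")
    )
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  out[order(-abs(out$cohens_d)), ]
}
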