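# Statistical kernels: BH-FDR, rank-sum, Spearman and partial Spearman,
# sign-fraction binomial test, p-value distribution comparison.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `adj_(i) = min_{j >= i} m * p_(j) / j`, clipped to 1,
#' returned in the input order. Thin validated wrapper over
#' `stats::p.adjust(method = "BH")`. `NA` p-values propagate as `NA` and do
#' not count toward `m`.
#'
#' @param pvalues Numeric vector of p-values in \[0,1\] (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; normal approximation with tie correction (and
#' continuity correction) otherwise. Groups smaller than 3 non-missing
#' values yield a flagged result with `p = NA`, which callers exclude from
#' FDR correction.
#'
#' @param a,b Numeric vectors (the two groups); `NA` dropped.
#' @return List with `statistic` (Mann-Whitney U for group `a`), `p`, and
#'   `ok` (logical: groups large enough).
#' @export
rank_sum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L) {
    return(list(statistic = NA_real_, p = NA_real_, ok = FALSE))
  }
  exact <- (length(a) + length(b) <= 20L) && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p = ht$p.value, ok = TRUE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p from `t = r * sqrt((n-2)/(1-r^2))`
#' on n-2 degrees of freedom. Pairs with a missing value in either vector
#' are removed; fewer than 5 complete pairs (or a constant vector) yields a
#' flagged missing result.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p`, `n`, `ok`.
#' @export
spearman_cor <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, ok = FALSE))
  }
  r <- stats::cor(rank(x), rank(y))
  list(r = r, p = t_pvalue_for_r(r, n, df = n - 2L), n = n, ok = TRUE)
}

t_pvalue_for_r <- function(r, n, df) {
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tval), df = df)
}

#' First-order partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and the covariate `z` (average ranks), then
#' applies the first-order partial correlation formula
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`;
#' two-sided p from a t distribution with n-3 degrees of freedom. A
#' covariate perfectly correlated with `x` or `y` (|r| = 1), or a constant
#' covariate, is degenerate and yields a flagged missing result.
#'
#' @param x,y Numeric vectors; `z` numeric or binary covariate of the same
#'   length.
#' @return List with `r`, `p`, `n`, `ok`, and `degenerate` (why, or `""`).
#' @export
partial_spearman <- function(x, y, z) {
  keep <- stats::complete.cases(x, y, z)
  x <- x[keep]; y <- y[keep]; z <- as.numeric(z[keep])
  n <- length(x)
  if (n < 5L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, ok = FALSE,
                degenerate = "too few pairs or constant margin"))
  }
  if (stats::sd(z) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, ok = FALSE,
                degenerate = "constant covariate"))
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_xy <- stats::cor(rx, ry); r_xz <- stats::cor(rx, rz); r_yz <- stats::cor(ry, rz)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    return(list(r = NA_real_, p = NA_real_, n = n, ok = FALSE,
                degenerate = "covariate collinear with a margin"))
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r <- max(-1, min(1, r))
  list(r = r, p = t_pvalue_for_r(r, n, df = n - 3L), n = n, ok = TRUE,
       degenerate = "")
}

#' Exact binomial test on the fraction of negative correlations
#'
#' Among significant correlations, tests whether the number with negative
#' sign departs from the 50:50 split expected when direction is arbitrary
#' (two-sided exact binomial at p0 = 0.5). A negative sign means the gene
#' is more essential where the partner's expression is higher.
#'
#' @param results data.frame of association results with columns `direction`
#'   (+1/-1) and `fdr_p`, or a numeric vector of directions.
#' @param alpha Significance cutoff on `fdr_p` when a data.frame is given
#'   (default 0.05).
#' @return List with `n`, `n_negative`, `fraction_negative`, `p`, `ok`.
#' @export
sign_fraction_test <- function(results, alpha = 0.05) {
  dirs <- if (is.data.frame(results)) {
    keep <- !is.na(results$fdr_p) & results$fdr_p < alpha
    results$direction[keep]
  } else as.numeric(results)
  dirs <- dirs[!is.na(dirs) & dirs != 0]
  n <- length(dirs)
  if (n == 0L) {
    return(list(n = 0L, n_negative = 0L, fraction_negative = NA_real_,
                p = NA_real_, ok = FALSE))
  }
  neg <- sum(dirs < 0)
  ht <- stats::binom.test(neg, n, p = 0.5, alternative = "two.sided")
  list(n = n, n_negative = neg, fraction_negative = neg / n,
       p = ht$p.value, ok = TRUE)
}

#' Compare two collections of p-values
#'
#' Rank-sum comparison of the p-value distributions of two gene groups
#' (e.g., FDR-corrected media-association p-values of metabolic versus
#' non-metabolic genes). Delegates to [rank_sum_test()].
#'
#' @param group_a,group_b Numeric vectors of p-values (`NA` dropped).
#' @return As [rank_sum_test()].
#' @export
compare_pvalue_distributions <- function(group_a, group_b) {
  rank_sum_test(group_a, group_b)
}
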