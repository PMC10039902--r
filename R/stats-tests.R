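#' Pearson correlation with argument checking
#'
#' @param x,y equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' differ in length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in 'x' or 'y'")
  stats::cor(x, y, method = "pearson")
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1), upper
#' tail of the chi-squared distribution. The p-value is reported at full
#' precision and rounded to three decimals, the reporting convention used
#' for clinical class comparisons.
#'
#' @param counts matrix of non-negative counts with positive margins and
#'   positive expected counts.
#' @return list with `statistic`, `df`, `p`, `p_rounded`.
#' @examples
#' sex_by_class <- rbind(female = c(9, 29, 15), male = c(11, 9, 13))
#' chiSquaredTest(sex_by_class)$p_rounded  # 0.037
#' @export
chiSquaredTest <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("expected counts must be positive")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, p_rounded = round(res$p.value, 3))
}

#' Games-Howell pairwise post-hoc comparisons
#'
#' Pairwise comparisons after a one-way layout with unequal variances: for
#' each pair of groups, `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom, and the p-value is the upper tail
#' of the studentized-range distribution with `k` groups evaluated at
#' `q = |t| * sqrt(2)`.
#'
#' @param groups named list of numeric vectors, each n >= 2 with nonzero
#'   variance.
#' @return data.frame, one row per unordered pair: `group1`, `group2`,
#'   `mean_diff`, `t`, `df`, `p`.
#' @export
gamesHowell <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("singleton group")
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) stop("zero variance group")
  m <- vapply(groups, mean, numeric(1))
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    tstat <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                   (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    c(mean_diff = unname(m[i] - m[j]), t = unname(tstat),
      df = unname(df), p = unname(p))
  })
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             t(res))
}
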