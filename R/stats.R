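#' Two-sided Wilcoxon rank-sum test
#'
#' Nonparametric two-sample comparison on pooled ranks. The p-value route is
#' chosen by sample size and ties, and is switchable:
#' * `exact = TRUE` (default when combined n <= 20 and the pooled sample has
#'   no ties): the exact null distribution of the Mann-Whitney U statistic,
#'   two-sided p = min(1, 2 * min(P(U <= u), P(U >= u))).
#' * otherwise: normal approximation with tie-corrected variance and a 0.5
#'   continuity correction. Degenerate variance (all pooled values equal)
#'   yields p = 1.
#'
#' The reported statistic is the rank sum W of `group_a` in the pooled
#' ranking (W = U + n_a(n_a + 1)/2).
#'
#' @param group_a,group_b Non-empty numeric vectors (missing values must be
#'   removed upstream).
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) route;
#'   `NULL` (default) picks exact iff combined n <= 20 and there are no
#'   ties.
#' @return List with `statistic` (rank sum of `group_a`), `u` (Mann-Whitney
#'   U), `p_value`, and `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
rank_sum_test <- function(group_a, group_b, exact = NULL) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values must be removed upstream")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (is.null(exact)) exact <- (n1 + n2 <= 20L) && !ties
  if (exact && ties)
    stop("exact p-value not available with tied observations")

  if (exact) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- table(pooled)
    tie_term <- sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- U - mu
      z <- (d - sign(d) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  list(statistic = W, u = U, p_value = p, method = method)
}

#' Median and interquartile range
#'
#' Summary pair used for reporting feature distributions. Quartiles use
#' linear interpolation between order statistics (R's default quantile
#' type 7); the convention is stated because IQR values depend on it for
#' small samples.
#'
#' @param values Non-empty numeric vector (NAs dropped with a warning if
#'   present).
#' @return Named numeric vector `c(median = ..., iqr = ...)`.
#' @export
median_iqr <- function(values) {
  if (anyNA(values)) {
    warning("dropping ", sum(is.na(values)), " missing value(s)")
    values <- values[!is.na(values)]
  }
  if (length(values) < 1L) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Compare one feature between cycle phases
#'
#' Splits a feature table into PP and LP groups, drops missing feature
#' values, and tests for a distributional difference with the two-sided
#' Wilcoxon rank-sum test at level `alpha`. Each segment is treated as an
#' independent sample (segments from one recording are in truth correlated;
#' this replicates the standard protocol — see the methods vignette).
#'
#' @param features Data frame with a `phase` column (`"PP"`/`"LP"`) and the
#'   feature column, as produced by [extract_features()] / [run_study()].
#' @param feature_name Feature column to compare (see [feature_names()]).
#' @param alpha Significance level (default 0.05).
#' @param exact Passed to [rank_sum_test()].
#' @return Object of class `eug_comparison`: list with `feature_name`,
#'   group sizes, `median_pp`, `iqr_pp`, `median_lp`, `iqr_lp`,
#'   `rank_sum_statistic`, `p_value`, `significant`, and `direction`
#'   (`"PP>LP"`, `"LP>PP"` or `"none"`, by median difference).
#' @export
compare_phases <- function(features, feature_name, alpha = 0.05,
                           exact = NULL) {
  if (!feature_name %in% names(features))
    stop("feature `", feature_name, "` not present in the table")
  if (!"phase" %in% names(features)) stop("table has no `phase` column")
  pp <- features[features$phase == "PP", feature_name]
  lp <- features[features$phase == "LP", feature_name]
  pp <- pp[!is.na(pp)]; lp <- lp[!is.na(lp)]
  if (length(pp) < 1L) stop("no PP samples for feature `", feature_name, "`")
  if (length(lp) < 1L) stop("no LP samples for feature `", feature_name, "`")

  ts <- rank_sum_test(pp, lp, exact = exact)
  mp <- median_iqr(pp); ml <- median_iqr(lp)
  dmed <- mp[["median"]] - ml[["median"]]
  structure(list(
    feature_name = feature_name,
    n_pp = length(pp), n_lp = length(lp),
    median_pp = mp[["median"]], iqr_pp = mp[["iqr"]],
    median_lp = ml[["median"]], iqr_lp = ml[["iqr"]],
    rank_sum_statistic = ts$statistic,
    p_value = ts$p_value,
    method = ts$method,
    alpha = alpha,
    significant = ts$p_value < alpha,
    direction = if (dmed > 0) "PP>LP" else if (dmed < 0) "LP>PP" else "none"
  ), class = "eug_comparison")
}

#' @export
print.eug_comparison <- function(x, ...) {
  cat(sprintf(
    "%-12s PP %.4g (%.4g) vs LP %.4g (%.4g)  [median (IQR), n = %d/%d]  W = %g, p = %.3g%s (%s)\n",
    x$feature_name, x$median_pp, x$iqr_pp, x$median_lp, x$iqr_lp,
    x$n_pp, x$n_lp, x$rank_sum_statistic, x$p_value,
    if (x$significant) " *" else "", x$direction))
  invisible(x)
}

#' Collect phase comparisons into a data frame
#'
#' @param comparisons List of `eug_comparison` objects.
#' @return Data frame, one row per feature.
#' @export
comparison_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(x) {
    data.frame(feature = x$feature_name, n_pp = x$n_pp, n_lp = x$n_lp,
               median_pp = x$median_pp, iqr_pp = x$iqr_pp,
               median_lp = x$median_lp, iqr_lp = x$iqr_lp,
               rank_sum_W = x$rank_sum_statistic, p_value = x$p_value,
               method = x$method, significant = x$significant,
               direction = x$direction, stringsAsFactors = FALSE)
  }))
}
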