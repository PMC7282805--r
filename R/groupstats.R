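#' Mann-Whitney U test for two independent samples
#'
#' Behavioural and regional c-fos metrics are generally not normally
#' distributed across fish, so group comparisons use the non-parametric
#' Mann-Whitney U test throughout. The U statistic is computed from midrank
#' sums; the two-sided p-value is exact (permutation distribution) for
#' small tie-free samples and a normal approximation with tie and
#' continuity correction otherwise.
#'
#' `mode = "auto"` selects the exact test when `n_a + n_b <= 16` and the
#' pooled sample is tie-free, matching common practice of exact small-sample
#' inference; `"exact"` and `"approx"` force a method (exact with ties is
#' refused rather than silently approximated).
#'
#' @param x,y numeric samples for the two groups.
#' @param mode `"auto"`, `"exact"`, or `"approx"`.
#' @param group_a,group_b labels recorded in the result.
#' @param metric name of the compared quantity.
#' @return object of class `group_comparison`: `metric`, `group_a`,
#'   `group_b`, `n_a`, `n_b`, `u_statistic` (U for `x`), `p_value`,
#'   `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx"),
                           group_a = "a", group_b = "b", metric = "metric") {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples contain NA", call. = FALSE)
  n_a <- length(x); n_b <- length(y)
  r <- rank(c(x, y))  # midranks
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    auto = (n_a + n_b <= 16) && !has_ties,
    exact = TRUE,
    approx = FALSE
  )
  if (exact && has_ties) {
    stop("exact p-value unavailable with tied values; use mode = 'approx'",
         call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  structure(list(
    metric = metric, group_a = group_a, group_b = group_b,
    n_a = n_a, n_b = n_b, u_statistic = u_a,
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal-approximation"
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s (n=%d) vs %s (n=%d), U = %g, p = %.3g (%s)\n",
              x$metric, x$group_a, x$n_a, x$group_b, x$n_b,
              x$u_statistic, x$p_value, x$method))
  invisible(x)
}

#' Comparison table across several metrics
#'
#' Runs [mann_whitney_u()] for each metric column shared by two per-fish
#' metric tables and assembles a tidy comparison table. A Benjamini-
#' Hochberg adjusted column is appended as an annotation (the per-comparison
#' p-values remain the primary report).
#'
#' @param df_a,df_b data.frames of per-fish metrics (one row per fish).
#' @param metrics character vector of metric column names.
#' @param group_a,group_b group labels.
#' @return data.frame: `metric`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `u_statistic`, `p_value`, `method`, `p_adjusted_bh`.
#' @export
compare_groups <- function(df_a, df_b, metrics,
                           group_a = "a", group_b = "b") {
  rows <- lapply(metrics, function(m) {
    cmp <- mann_whitney_u(df_a[[m]], df_b[[m]], mode = "auto",
                          group_a = group_a, group_b = group_b, metric = m)
    data.frame(metric = m, group_a = group_a, group_b = group_b,
               n_a = cmp$n_a, n_b = cmp$n_b, u_statistic = cmp$u_statistic,
               p_value = cmp$p_value, method = cmp$method)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
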