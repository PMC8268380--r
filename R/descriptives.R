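# Two-group descriptive comparisons: Pearson chi-square for categorical
# variables, two-sample t for continuous ones, with per-outcome missing-data
# accounting.

#' Pearson chi-square comparison of a 2 x k contingency table
#'
#' Computes the Pearson chi-square statistic with (k - 1) degrees of freedom
#' and its p-value, without continuity correction (the intended use is large
#' administrative cohorts). A warning is emitted when any expected cell count
#' falls below 5.
#'
#' @param counts a 2 x k matrix of non-negative counts; rows are the two
#'   groups, columns the variable levels.
#' @param variable optional variable name for labelling.
#' @return An object of class `margpath_comparison` with fields `variable`,
#'   `test = "Pearson chi-square"`, `statistic`, `df`, `p_value`, `counts`,
#'   `percentages` (within-group, summing to 100 per group).
#' @examples
#' compare_categorical(rbind(nonobese = c(1419, 33644 - 1419),
#'                           obese = c(526, 8411 - 526)))
#' @export
compare_categorical <- function(counts, variable = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L || ncol(counts) < 2L) {
    stop("counts must be a 2 x k table with k >= 2")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero-margin table: every row and column total must be positive")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    warning("expected cell count below 5; chi-square approximation may be poor")
  }
  stat <- sum((counts - expected)^2 / expected)
  df <- ncol(counts) - 1L
  structure(list(
    variable = variable, test = "Pearson chi-square",
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    counts = counts,
    percentages = 100 * counts / rowSums(counts),
    n_missing = c(0L, 0L)),
    class = "margpath_comparison")
}

#' Two-sample t comparison of a continuous outcome
#'
#' Classical pooled-variance two-sample t test (group standard deviations in
#' discharge data are near-equal; Welch is available via `pooled = FALSE`).
#' Missing values are excluded listwise for this outcome and counted per
#' group. The degenerate case — zero variance in both groups — returns p = 1
#' when the means are equal and p = 0 otherwise, rather than NaN.
#'
#' @param x,y numeric outcome values in the two groups (NAs allowed).
#' @param variable optional variable name.
#' @param pooled use the pooled-variance statistic (default) or Welch.
#' @return A `margpath_comparison` with `statistic` (t), `df`, `p_value`, and
#'   per-group `mean`, `sd`, `median`, `n`, `n_missing`.
#' @export
compare_continuous <- function(x, y, variable = NULL, pooled = TRUE) {
  n_missing <- c(sum(is.na(x)), sum(is.na(y)))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 non-missing values per group")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    tt <- list(statistic = if (eq) 0 else Inf,
               parameter = length(x) + length(y) - 2,
               p.value = if (eq) 1 else 0)
  } else {
    tt <- stats::t.test(x, y, var.equal = pooled)
  }
  structure(list(
    variable = variable, test = "two-sample t",
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)),
    median = c(stats::median(x), stats::median(y)),
    n = c(length(x), length(y)), n_missing = n_missing),
    class = "margpath_comparison")
}

#' @export
print.margpath_comparison <- function(x, ...) {
  cat("<margpath_comparison> ", x$test,
      if (!is.null(x$variable)) paste0(" [", x$variable, "]"), "\n", sep = "")
  if (x$test == "Pearson chi-square") {
    cat("  X-squared =", format(x$statistic), " df =", x$df,
        " p =", format.pval(x$p_value, digits = 4), "\n")
  } else {
    cat(sprintf("  group means %s vs %s (t = %s, df = %s, p = %s)\n",
                format(x$mean[1], digits = 4), format(x$mean[2], digits = 4),
                format(x$statistic, digits = 4), format(x$df),
                format.pval(x$p_value, digits = 4)))
  }
  invisible(x)
}

#' Two-group comparison table for a set of variables
#'
#' Builds a publication-shaped long table: per categorical variable, counts
#' and within-group percentages by level with one Pearson chi-square p-value;
#' per continuous variable, mean, SD and median by group with a two-sample t
#' p-value and per-group missing counts.
#'
#' @param rows `data.frame` of analytic rows.
#' @param group logical vector (TRUE = second group, e.g. exposed) aligned
#'   with `rows`.
#' @param vars variable names in `rows`; logicals and characters/factors are
#'   treated as categorical, numerics as continuous.
#' @param group_labels length-2 labels, first for `group == FALSE`.
#' @return `data.frame` with columns `variable`, `level`, per-group `n`/`pct`
#'   (or `mean`/`sd`/`median`), `test`, `statistic`, `p_value`,
#'   `significant` (p < 0.05), `n_missing_1`, `n_missing_2`.
#' @export
comparison_table <- function(rows, group, vars,
                             group_labels = c("group1", "group2")) {
  stopifnot(length(group) == nrow(rows))
  out <- list()
  for (v in vars) {
    x <- rows[[v]]
    if (is.null(x)) stop("variable not found: ", v)
    if (is.numeric(x) && !is.logical(x)) {
      cmp <- compare_continuous(x[!group], x[group], variable = v)
      out[[v]] <- data.frame(
        variable = v, level = "",
        n_1 = cmp$n[1], stat_1 = sprintf("%.2f ± %.2f (md %s)",
                                         cmp$mean[1], cmp$sd[1],
                                         format(cmp$median[1])),
        n_2 = cmp$n[2], stat_2 = sprintf("%.2f ± %.2f (md %s)",
                                         cmp$mean[2], cmp$sd[2],
                                         format(cmp$median[2])),
        test = cmp$test, statistic = cmp$statistic, p_value = cmp$p_value,
        significant = cmp$p_value < 0.05,
        n_missing_1 = cmp$n_missing[1], n_missing_2 = cmp$n_missing[2],
        stringsAsFactors = FALSE)
    } else {
      xf <- factor(x)
      tab <- rbind(table(xf[!group]), table(xf[group]))
      cmp <- if (ncol(tab) >= 2) compare_categorical(tab, variable = v) else NULL
      lv <- levels(xf)
      out[[v]] <- data.frame(
        variable = v, level = lv,
        n_1 = as.integer(tab[1, ]),
        stat_1 = sprintf("%.2f%%", 100 * tab[1, ] / sum(tab[1, ])),
        n_2 = as.integer(tab[2, ]),
        stat_2 = sprintf("%.2f%%", 100 * tab[2, ] / sum(tab[2, ])),
        test = if (is.null(cmp)) NA_character_ else cmp$test,
        statistic = if (is.null(cmp)) NA_real_ else cmp$statistic,
        p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
        significant = if (is.null(cmp)) NA else cmp$p_value < 0.05,
        n_missing_1 = sum(is.na(x[!group])), n_missing_2 = sum(is.na(x[group])),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "group_labels") <- group_labels
  rownames(res) <- NULL
  res
}
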