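#' Rescale values to quartile labels
#'
#' Maps each value to its quartile of the observed distribution: label 1 for
#' values at or below the first quartile, 2 up to the median, 3 up to the
#' third quartile, 4 above. Quartiles are linear-interpolation (type-7)
#' quantiles; tied values share the lower label.
#'
#' @param values Numeric vector, length >= 4.
#' @return Integer labels in 1-4.
#' @export
quartile_rescale <- function(values) {
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7)
  1L + (values > q[1]) + (values > q[2]) + (values > q[3])
}

#' Pearson chi-square test of a contingency table
#'
#' Plain Pearson test without continuity correction, with Pearson residuals
#' `(observed - expected) / sqrt(expected)`.
#'
#' @param table Matrix or table of nonnegative counts.
#' @return List with `statistic`, `df`, `p.value`, `residuals`, `expected`.
#' @export
chi2_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: drop empty rows/columns before testing", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, residuals = ct$residuals, expected = ct$expected)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H over two or more groups, with the p-value
#' from the chi-square tail on k - 1 degrees of freedom. If all observations
#' are identical the statistic is 0 by convention (with a warning), since
#' the tie correction is degenerate.
#'
#' @param groups List of numeric vectors (>= 2 nonempty groups, total
#'   n >= 3).
#' @return List with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need >= 2 nonempty groups", call. = FALSE)
  x <- unlist(groups)
  if (length(x) < 3) stop("need total n >= 3", call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    warning("all observations identical; H = 0 by convention")
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}
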