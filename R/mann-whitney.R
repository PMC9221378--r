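#' Two-sided Mann-Whitney U test between two groups
#'
#' Wraps [stats::wilcox.test()] with the conventions used throughout the
#' package: the exact null distribution when both groups have at most
#' `exact_max` observations and the pooled values are untied, and the normal
#' approximation with tie correction (and continuity correction) otherwise.
#' Both compared groups must have at least 3 observations.
#'
#' @param x,y Numeric vectors of the two groups.
#' @param exact_max Largest group size for which the exact distribution is
#'   used (default 8).
#' @return List with `U` (the Mann-Whitney statistic of `x`), `p` (two-sided
#'   p-value), `exact` (logical), and `stars` (see [signif_stars()]).
#' @export
mw_test <- function(x, y, exact_max = 8) {
  if (length(x) < 3 || length(y) < 3)
    stop("mw_test: untestable pair (each group needs >= 3 observations)")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = use_exact,
       stars = signif_stars(wt$p.value))
}

#' Mann-Whitney significance matrix over features and class pairs
#'
#' Runs [mw_test()] for every feature column and every pair of classes (in
#' canonical order), attaching the star labels `***`/`**`/`*`/`NS` at the
#' 0.001/0.01/0.05 thresholds. No multiple-testing correction is applied.
#'
#' @param features Matrix or data frame of feature columns, rows = samples.
#' @param grouping Class label per row.
#' @param feature_cols Columns to test (default: all numeric columns).
#' @return A `significance_table` data frame: `feature`, `group1`, `group2`,
#'   `n1`, `n2`, `U`, `p_value`, `signif`.
#' @export
mann_whitney_matrix <- function(features, grouping,
                                feature_cols = NULL) {
  features <- as.data.frame(features)
  grouping <- as_class_factor(grouping)
  feature_cols <- feature_cols %||%
    names(features)[vapply(features, is.numeric, logical(1))]
  classes <- levels(grouping)[table(grouping)[levels(grouping)] > 0]
  if (length(classes) < 2)
    stop("mann_whitney_matrix: need at least two classes")
  pairs <- utils::combn(classes, 2)
  rows <- list()
  for (f in feature_cols) {
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      xa <- features[grouping == a, f]; xb <- features[grouping == b, f]
      if (length(xa) < 3 || length(xb) < 3)
        stop("mann_whitney_matrix: untestable pair ", a, " vs ", b,
             " (fewer than 3 samples per group)")
      t <- mw_test(xa, xb)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group1 = a, group2 = b,
        n1 = length(xa), n2 = length(xb),
        U = t$U, p_value = t$p, signif = t$stars,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("significance_table", "data.frame")
  out
}

#' @export
print.significance_table <- function(x, ...) {
  cat(sprintf("<significance_table> %d tests (%s)\n", nrow(x),
              "*** p<0.001, ** p<0.01, * p<0.05, NS otherwise"))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
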