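# Coerce a 2x2 count input (matrix, data frame, or length-4 vector a,b,c,d
# in row-major order) to a validated integer matrix with dimnames.
as_table_2x2 <- function(x, group_labels = NULL, outcome_labels = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && length(x) == 4) {
    x <- matrix(x, nrow = 2, byrow = TRUE)
  }
  if (!is.matrix(x) || !all(dim(x) == c(2, 2))) {
    abort("Expected a 2x2 table of counts.")
  }
  storage.mode(x) <- "double"
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    abort("Counts must be non-negative integers.")
  }
  rownames(x) <- group_labels %||% rownames(x) %||% c("group1", "group2")
  colnames(x) <- outcome_labels %||% colnames(x) %||% c("positive", "negative")
  x
}

#' Chi-squared association test for a 2x2 cohort table
#'
#' Pearson chi-squared test (df = 1) of association between a two-level
#' grouping (e.g. low vs high gamma-tubulin staining) and a two-level outcome
#' (e.g. low vs high PCNA staining), with the odds ratio `(a d)/(b c)`. The
#' continuity correction is off by default and available via `yates = TRUE`;
#' the uncorrected statistic is the classic Pearson formula
#' `sum((O - E)^2 / E)`. The test requires every row and column margin to be
#' positive; a zero cell is allowed and flags the odds ratio as degenerate
#' (0 or Inf).
#'
#' @param x A 2x2 matrix or data frame of counts (rows = groups, columns =
#'   outcome levels, first column = "high"/positive), or a length-4 vector
#'   `c(a, b, c, d)` in row-major order.
#' @param yates Apply the Yates continuity correction? Default `FALSE`.
#' @param group_labels,outcome_labels Optional dimension labels.
#' @return A `coloc_chisq` object: `statistic`, `df`, `p_value`,
#'   `correction_used`, `odds_ratio`, `zero_cell`, `table`. `glance()` and
#'   `tidy()` return a one-row tibble.
#' @examples
#' chi2_2x2(matrix(c(38, 19, 79, 11), nrow = 2, byrow = TRUE),
#'          group_labels = c("low_TUBG", "high_TUBG"),
#'          outcome_labels = c("pcna_high", "pcna_low"))
#' @export
chi2_2x2 <- function(x, yates = FALSE, group_labels = NULL,
                     outcome_labels = NULL) {
  m <- as_table_2x2(x, group_labels, outcome_labels)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Every row and column margin must be positive for the chi-squared test.")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = yates))
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  zero_cell <- any(m == 0)
  or <- (a * d) / (b * c) # 0/Inf (or NaN for two zero cells) when degenerate
  structure(
    list(
      statistic = unname(ht$statistic),
      df = 1L,
      p_value = unname(ht$p.value),
      correction_used = yates,
      odds_ratio = unname(or),
      zero_cell = zero_cell,
      table = m
    ),
    class = "coloc_chisq"
  )
}

#' @export
print.coloc_chisq <- function(x, ...) {
  cat(sprintf("2x2 chi-squared association test%s\n",
              if (x$correction_used) " (Yates-corrected)" else ""))
  print(x$table)
  cat(sprintf("  X-squared = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  odds ratio = %.4g%s\n", x$odds_ratio,
              if (x$zero_cell) "  [zero cell: degenerate]" else ""))
  invisible(x)
}

#' @rdname chi2_2x2
#' @param ... Unused.
#' @method glance coloc_chisq
#' @export
glance.coloc_chisq <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    correction_used = x$correction_used, odds_ratio = x$odds_ratio,
    zero_cell = x$zero_cell
  )
}

#' @rdname chi2_2x2
#' @method tidy coloc_chisq
#' @export
tidy.coloc_chisq <- function(x, ...) glance(x)

#' Per-group outcome proportions of a 2x2 table
#'
#' Fraction of each group in the first (positive/"high") outcome column,
#' with the counts echoed.
#'
#' @inheritParams chi2_2x2
#' @return A tibble with one row per group: `group`, `n`, `n_positive`,
#'   `fraction_positive`.
#' @examples
#' group_proportions(matrix(c(38, 19, 79, 11), nrow = 2, byrow = TRUE))
#' @export
group_proportions <- function(x, group_labels = NULL, outcome_labels = NULL) {
  m <- as_table_2x2(x, group_labels, outcome_labels)
  n <- rowSums(m)
  if (any(n == 0)) abort("Every group must contain at least one subject.")
  tibble(
    group = rownames(m),
    n = unname(n),
    n_positive = unname(m[, 1]),
    fraction_positive = unname(m[, 1] / n)
  )
}

#' Read a 2x2 cohort table from CSV
#'
#' Expects a header and two data rows: `group,<positive>,<negative>` with the
#' positive/"high" outcome in the second column. The packaged file
#' `system.file("extdata", "ovarian_cohort_counts.csv", package = "peakcoloc")`
#' holds the published ovarian-cohort counts.
#'
#' @param path CSV file path.
#' @return A labelled 2x2 count matrix.
#' @export
read_cohort_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || nrow(df) != 2) {
    abort("Cohort CSV must have 2 rows and columns: group, positive, negative.")
  }
  as_table_2x2(as.matrix(df[, 2:3]),
               group_labels = as.character(df[[1]]),
               outcome_labels = colnames(df)[2:3])
}
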