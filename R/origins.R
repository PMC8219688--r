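#' Classify licensed replication origins as active or dormant
#'
#' Origins licensed by the replicative helicase are taken to be the Mcm peak
#' set; an origin counts as *active* (fired) when its Mcm peak overlaps at
#' least one PCNA (sliding clamp) peak under the span-fraction criterion —
#' reciprocal 25% by default, i.e. the shared span covers at least a quarter
#' of both peaks — and *dormant* otherwise. The two classes partition the
#' input exactly, preserving order and coordinates.
#'
#' @param mcm Peak tibble of licensed-origin (Mcm) peaks.
#' @param pcna Peak tibble of clamp-loaded (PCNA) peaks.
#' @inheritParams count_overlapped
#' @return An `origin_classes` object: peak tibbles `active` and `dormant`,
#'   counts `n_active`/`n_dormant`, and the criterion used. `tidy()` returns
#'   the Mcm table with an `origin_class` column.
#' @examples
#' g <- chrom_sizes("chrT", 2000)
#' mcm <- as_peaks(data.frame(chrom = "chrT",
#'                            start = c(0, 500, 900), end = c(200, 700, 1100)), g)
#' pcna <- as_peaks(data.frame(chrom = "chrT", start = 100, end = 300), g)
#' classify_origins(mcm, pcna)
#' @export
classify_origins <- function(mcm, pcna, genome = NULL,
                             mode = c("reciprocal", "query_fraction", "reference_fraction"),
                             threshold = 0.25) {
  mode <- match.arg(mode)
  check_threshold(threshold)
  check_same_genome(mcm, pcna, genome)
  pairs <- overlap_pairs(mcm, pcna, mode, threshold)
  is_active <- seq_len(nrow(mcm)) %in% pairs$query_idx
  structure(
    list(
      active = mcm[is_active, , drop = FALSE],
      dormant = mcm[!is_active, , drop = FALSE],
      n_active = sum(is_active),
      n_dormant = sum(!is_active),
      mode = mode,
      threshold = threshold,
      mcm_label = peak_label(mcm),
      pcna_label = peak_label(pcna)
    ),
    class = "origin_classes"
  )
}

#' @export
print.origin_classes <- function(x, ...) {
  n <- x$n_active + x$n_dormant
  cat(sprintf("Origin classification (%s vs %s, %s threshold %.2f):\n",
              x$mcm_label, x$pcna_label, x$mode, x$threshold))
  cat(sprintf("  active:  %d / %d (%.1f%%)\n", x$n_active, n,
              if (n > 0) 100 * x$n_active / n else NA_real_))
  cat(sprintf("  dormant: %d / %d\n", x$n_dormant, n))
  invisible(x)
}

#' @rdname classify_origins
#' @param x An `origin_classes` object.
#' @param ... Unused.
#' @method tidy origin_classes
#' @export
tidy.origin_classes <- function(x, ...) {
  out <- dplyr::bind_rows(
    dplyr::mutate(x$active, origin_class = "active"),
    dplyr::mutate(x$dormant, origin_class = "dormant")
  )
  dplyr::arrange(out, match(.data$chrom, unique(out$chrom)), .data$start, .data$end)
}

#' @rdname classify_origins
#' @method glance origin_classes
#' @export
glance.origin_classes <- function(x, ...) {
  n <- x$n_active + x$n_dormant
  tibble(
    mcm_label = x$mcm_label, pcna_label = x$pcna_label,
    mode = x$mode, threshold = x$threshold,
    n_origins = n, n_active = x$n_active, n_dormant = x$n_dormant,
    fraction_active = if (n > 0) x$n_active / n else NA_real_
  )
}

#' Coverage of an origin class by a query factor
#'
#' Fraction of the peaks of one origin class that are overlapped by at least
#' one query peak (e.g. what share of active origins carry a gamma-tubulin
#' peak). The direction can be flipped with `direction = "of_query"` to
#' report the share of query peaks that land on the class.
#'
#' @param query Peak tibble of the covering factor.
#' @param class_peaks Peak tibble of one origin class (e.g. `x$active` from
#'   [classify_origins()]).
#' @param class_label Label used in the report.
#' @param direction `"of_class"` (default): fraction of class peaks covered;
#'   `"of_query"`: fraction of query peaks overlapping the class.
#' @inheritParams count_overlapped
#' @return A one-row tibble: `query_label`, `class_label`, `n_class`,
#'   `n_covered`, `fraction_covered`, `empty_class`. An empty class yields
#'   fraction 0 with `empty_class = TRUE`.
#' @export
class_coverage <- function(query, class_peaks, class_label = "class",
                           genome = NULL,
                           mode = c("reciprocal", "query_fraction", "reference_fraction"),
                           threshold = 0.25,
                           direction = c("of_class", "of_query")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  check_threshold(threshold)
  check_same_genome(query, class_peaks, genome)
  ov <- count_overlapped(query, class_peaks, genome = genome,
                         mode = mode, threshold = threshold)
  if (direction == "of_class") {
    n_class <- ov$n_reference
    n_covered <- ov$n_reference_overlapped
  } else {
    n_class <- ov$n_query
    n_covered <- ov$n_query_overlapped
  }
  tibble(
    query_label = peak_label(query),
    class_label = class_label,
    n_class = n_class,
    n_covered = n_covered,
    fraction_covered = if (n_class > 0) n_covered / n_class else 0,
    empty_class = n_class == 0
  )
}

#' Coverage of both origin classes by one or more query factors
#'
#' @param query A peak tibble, or a named list of peak tibbles (one row pair
#'   per factor in the output).
#' @param classes An `origin_classes` object from [classify_origins()].
#' @inheritParams class_coverage
#' @return A tibble with one row per (query, class) combination, as in
#'   [class_coverage()].
#' @export
origin_coverage <- function(query, classes, genome = NULL,
                            mode = c("reciprocal", "query_fraction", "reference_fraction"),
                            threshold = 0.25,
                            direction = c("of_class", "of_query")) {
  stopifnot(inherits(classes, "origin_classes"))
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  queries <- if (is.data.frame(query)) list(query) else query
  purrr::map_dfr(queries, function(q) {
    dplyr::bind_rows(
      class_coverage(q, classes$active, "active", genome, mode, threshold, direction),
      class_coverage(q, classes$dormant, "dormant", genome, mode, threshold, direction)
    )
  })
}
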