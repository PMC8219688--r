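#' Pairwise overlap fractions between peaks
#'
#' For paired rows of `a` and `b` (recycled if one has a single row), computes
#' the intersection length `I = max(0, min(end_a, end_b) - max(start_a,
#' start_b))` (0 across chromosomes) and the fractions of each peak's width it
#' covers. These span fractions are the building block of the package's
#' overlap criterion: two peaks are called overlapping when the shared span
#' covers at least a threshold fraction (default 25%) of one or both widths.
#'
#' @param a,b Data frames of peaks (`chrom`, `start`, `end`) with equal row
#'   counts, or one of them a single row.
#' @return A tibble with columns `intersection`, `frac_a`, `frac_b`.
#' @examples
#' p <- function(s, e) data.frame(chrom = "c", start = s, end = e)
#' overlap_fraction(p(100, 200), p(150, 260)) # I = 50 -> 0.50, 0.4545
#' @export
overlap_fraction <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  rec <- function(x) if (nrow(x) == n) x else x[rep(1L, n), , drop = FALSE]
  a <- rec(a); b <- rec(b)
  inter <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  inter[a$chrom != b$chrom] <- 0
  tibble(
    intersection = inter,
    frac_a = inter / (a$end - a$start),
    frac_b = inter / (b$end - b$start)
  )
}

#' Do peaks overlap under a span-fraction criterion?
#'
#' Modes: `"reciprocal"` requires the shared span to cover at least
#' `threshold` of *both* widths; `"query_fraction"` only of the query peak
#' `a`; `"reference_fraction"` only of the reference peak `b`. The comparison
#' is inclusive (`>=`): "at least 25%" admits exactly 25%.
#'
#' @inheritParams overlap_fraction
#' @param mode Overlap mode; see Details.
#' @param threshold Span fraction in `(0, 1]`; default `0.25`.
#' @return Logical vector, one element per peak pair.
#' @export
peaks_overlap <- function(a, b,
                          mode = c("reciprocal", "query_fraction", "reference_fraction"),
                          threshold = 0.25) {
  mode <- match.arg(mode)
  check_threshold(threshold)
  fr <- overlap_fraction(a, b)
  switch(mode,
    reciprocal = fr$frac_a >= threshold & fr$frac_b >= threshold,
    query_fraction = fr$frac_a >= threshold,
    reference_fraction = fr$frac_b >= threshold
  )
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single number in (0, 1].")
  }
  invisible(threshold)
}

# Internal per-chromosome sweep. Given query and reference intervals on one
# chromosome (0-based half-open), returns indices (into the given vectors) of
# all pairs with positive intersection. References are sorted by start; a
# running maximum of sorted ends bounds the candidate window for each query,
# so the cost is near-linear in peaks plus true pairs.
pair_sweep <- function(qs, qe, rs, re) {
  nq <- length(qs)
  nr <- length(rs)
  if (nq == 0 || nr == 0) {
    return(list(qi = integer(0), ri = integer(0)))
  }
  o <- order(rs, re)
  rs_s <- rs[o]
  re_s <- re[o]
  cme <- cummax(re_s)
  k <- findInterval(qe - 1, rs_s)       # references with start < query end
  j <- findInterval(qs, cme) + 1L       # first candidate with end possibly > start
  len <- pmax(0L, k - j + 1L)
  qi <- rep.int(seq_len(nq), len)
  ri <- sequence(len, from = ifelse(len > 0L, j, 1L))
  keep <- re_s[ri] > qs[qi]
  list(qi = qi[keep], ri = o[ri[keep]])
}

# Internal: all qualifying pairs between two peak tables, as global row
# indices plus fractions. Used by count_overlapped(), the classifier and the
# permutation loop (via stat_counts() on raw splits).
overlap_pairs <- function(query, reference, mode, threshold) {
  qsp <- split_coords(query)
  rsp <- split_coords(reference)
  shared <- intersect(names(qsp), names(rsp))
  res <- lapply(shared, function(ch) {
    q <- qsp[[ch]]
    r <- rsp[[ch]]
    pp <- pair_sweep(q$start, q$end, r$start, r$end)
    if (length(pp$qi) == 0) return(NULL)
    inter <- pmin(q$end[pp$qi], r$end[pp$ri]) - pmax(q$start[pp$qi], r$start[pp$ri])
    fq <- inter / q$width[pp$qi]
    fr <- inter / r$width[pp$ri]
    ok <- switch(mode,
      reciprocal = fq >= threshold & fr >= threshold,
      query_fraction = fq >= threshold,
      reference_fraction = fr >= threshold
    )
    tibble(
      query_idx = q$idx[pp$qi][ok], ref_idx = r$idx[pp$ri][ok],
      intersection = inter[ok], frac_query = fq[ok], frac_ref = fr[ok]
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(query_idx = integer(0), ref_idx = integer(0),
                  intersection = numeric(0), frac_query = numeric(0),
                  frac_ref = numeric(0))
  }
  out
}

#' Count peaks overlapped between two sets
#'
#' A query peak counts as overlapped when at least one reference peak
#' satisfies the span-fraction criterion (see [peaks_overlap()]); the
#' reference direction and the number of qualifying pairs are reported too.
#' Matching uses a per-chromosome sorted sweep whose result is identical to
#' the all-pairs brute force.
#'
#' @param query,reference Peak tibbles (see [as_peaks()]). If both are bound
#'   to genomes, the genomes must match.
#' @param genome Optional genome tibble overriding the bound genomes.
#' @inheritParams peaks_overlap
#' @return A `coloc_overlap` object: counts (`n_query`, `n_reference`,
#'   `n_query_overlapped`, `n_reference_overlapped`, `n_pairs`), the matched
#'   pair table, and the criterion used. `tidy()` returns the pair table,
#'   `glance()` a one-row summary.
#' @examples
#' g <- chrom_sizes("chrT", 10000)
#' a <- as_peaks(data.frame(chrom = "chrT", start = c(0, 500), end = c(200, 800)), g)
#' count_overlapped(a, a)
#' @export
count_overlapped <- function(query, reference, genome = NULL,
                             mode = c("reciprocal", "query_fraction", "reference_fraction"),
                             threshold = 0.25) {
  mode <- match.arg(mode)
  check_threshold(threshold)
  check_same_genome(query, reference, genome)
  pairs <- overlap_pairs(query, reference, mode, threshold)
  structure(
    list(
      n_query = nrow(query),
      n_reference = nrow(reference),
      n_query_overlapped = length(unique(pairs$query_idx)),
      n_reference_overlapped = length(unique(pairs$ref_idx)),
      n_pairs = nrow(pairs),
      matched = pairs,
      mode = mode,
      threshold = threshold,
      query_label = peak_label(query),
      reference_label = peak_label(reference)
    ),
    class = "coloc_overlap"
  )
}

#' @export
print.coloc_overlap <- function(x, ...) {
  cat(sprintf(
    "Peak overlap (%s, threshold %.2f): %s vs %s\n",
    x$mode, x$threshold, x$query_label, x$reference_label
  ))
  cat(sprintf("  query overlapped:     %d / %d\n", x$n_query_overlapped, x$n_query))
  cat(sprintf("  reference overlapped: %d / %d\n", x$n_reference_overlapped, x$n_reference))
  cat(sprintf("  qualifying pairs:     %d\n", x$n_pairs))
  invisible(x)
}

#' @rdname count_overlapped
#' @param x A `coloc_overlap` object.
#' @param ... Unused.
#' @method tidy coloc_overlap
#' @export
tidy.coloc_overlap <- function(x, ...) x$matched

#' @rdname count_overlapped
#' @method glance coloc_overlap
#' @export
glance.coloc_overlap <- function(x, ...) {
  tibble(
    query_label = x$query_label, reference_label = x$reference_label,
    mode = x$mode, threshold = x$threshold,
    n_query = x$n_query, n_reference = x$n_reference,
    n_query_overlapped = x$n_query_overlapped,
    n_reference_overlapped = x$n_reference_overlapped,
    n_pairs = x$n_pairs,
    frac_query_overlapped =
      if (x$n_query > 0) x$n_query_overlapped / x$n_query else NA_real_
  )
}
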