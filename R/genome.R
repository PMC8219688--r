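#' Construct a genome model from chromosome names and lengths
#'
#' A genome model is a tibble with columns `chrom` and `length` (bp). It
#' defines the universe in which peaks live and in which randomized peaks are
#' re-placed: permutations never move a peak off its chromosome.
#'
#' @param chrom Character vector of unique, non-empty chromosome names.
#' @param length Numeric vector of chromosome lengths in bp, all `> 0`.
#'
#' @return A tibble with columns `chrom` (character) and `length` (numeric),
#'   one row per chromosome, in the order given.
#' @examples
#' chrom_sizes(c("chr1", "chr2"), c(5e7, 3e7))
#' @export
chrom_sizes <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    abort("`chrom` and `length` must have the same length.")
  }
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    abort("Chromosome names must be non-empty.")
  }
  if (anyDuplicated(chrom)) {
    abort(paste0(
      "Duplicate chromosome name(s): ",
      paste(unique(chrom[duplicated(chrom)]), collapse = ", ")
    ))
  }
  if (any(is.na(length)) || any(length <= 0) || any(length != floor(length))) {
    abort("Chromosome lengths must be positive integers.")
  }
  tibble(chrom = chrom, length = length)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Parses the two-column TAB-separated `name<TAB>length` format. Line order is
#' preserved. Malformed lines (non-integer or non-positive length, duplicated
#' names) raise an error naming the offending line.
#'
#' @param path Path to a chrom.sizes file.
#' @return A genome tibble as returned by [chrom_sizes()].
#' @examples
#' f <- tempfile()
#' writeLines(c("chrA\t500", "chrB\t2000"), f)
#' read_chrom_sizes(f)
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 2)) {
    bad <- lineno[which(n_fields < 2)[1]]
    abort(sprintf("chrom.sizes line %d: expected `name<TAB>length`.", bad))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  len_chr <- vapply(fields, `[[`, character(1), 2L)
  len <- suppressWarnings(as.numeric(len_chr))
  bad <- is.na(len) | len <= 0 | len != floor(len)
  if (any(bad)) {
    abort(sprintf(
      "chrom.sizes line %d: length '%s' is not a positive integer.",
      lineno[which(bad)[1]], len_chr[which(bad)[1]]
    ))
  }
  if (anyDuplicated(nm)) {
    abort(sprintf(
      "chrom.sizes: duplicate chromosome name '%s'.",
      nm[duplicated(nm)][1]
    ))
  }
  chrom_sizes(nm, len)
}

# Internal: validate a genome tibble (columns, invariants).
validate_genome <- function(genome, arg = "genome") {
  if (!is.data.frame(genome) || !all(c("chrom", "length") %in% names(genome))) {
    abort(sprintf("`%s` must be a data frame with columns `chrom` and `length`.", arg))
  }
  chrom_sizes(genome$chrom, genome$length)
}

# Internal: named vector chrom -> length.
genome_lengths <- function(genome) {
  stats::setNames(as.numeric(genome$length), as.character(genome$chrom))
}
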