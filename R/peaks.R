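#' Validate and normalize a peak table
#'
#' A peak set is a tibble with columns `chrom`, `start`, `end` (0-based,
#' half-open BED coordinates) and optionally `name` and `score`. `as_peaks()`
#' checks the interval invariants (`0 <= start < end`, and `end` within the
#' chromosome when a genome is supplied), sorts peaks by chromosome, start and
#' end, and attaches the genome and label as attributes so that downstream
#' operations can verify that two peak sets live in the same universe.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param genome Optional genome tibble (see [chrom_sizes()]). When supplied,
#'   every peak must lie on a known chromosome and inside its bounds.
#' @param label Optional label for the set (e.g. `"PCNA_1h"`), stored as an
#'   attribute and echoed in reports.
#' @param on_unknown_chrom What to do with peaks on chromosomes absent from
#'   `genome`: `"error"` (default) or `"drop"` (with a warning). Real peak
#'   files often carry unplaced scaffolds; dropping is opt-in.
#'
#' @return A sorted tibble of peaks with attributes `label` and `genome`.
#' @examples
#' g <- chrom_sizes("chrT", 1000)
#' as_peaks(data.frame(chrom = "chrT", start = c(500, 10), end = c(700, 200)), g)
#' @export
as_peaks <- function(x, genome = NULL, label = NULL,
                     on_unknown_chrom = c("error", "drop")) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort("Peaks must be a data frame with columns `chrom`, `start`, `end`.")
  }
  x <- as_tibble(x)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (any(is.na(x$start)) || any(is.na(x$end)) || any(is.na(x$chrom))) {
    abort("Peak coordinates and chromosome names must be non-missing.")
  }
  bad <- x$start < 0 | x$start >= x$end
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Invalid peak %s:%s-%s: need 0 <= start < end.",
      x$chrom[i], format(x$start[i], scientific = FALSE),
      format(x$end[i], scientific = FALSE)
    ))
  }
  chrom_levels <- unique(x$chrom)
  if (!is.null(genome)) {
    genome <- validate_genome(genome)
    unknown <- !(x$chrom %in% genome$chrom)
    if (any(unknown)) {
      if (on_unknown_chrom == "error") {
        abort(sprintf(
          "Peak(s) on chromosome(s) not in genome: %s. Use on_unknown_chrom = \"drop\" to discard.",
          paste(unique(x$chrom[unknown]), collapse = ", ")
        ))
      }
      warn(sprintf("Dropping %d peak(s) on unknown chromosome(s).", sum(unknown)))
      x <- x[!unknown, , drop = FALSE]
    }
    lens <- genome_lengths(genome)
    over <- x$end > lens[x$chrom]
    if (any(over)) {
      i <- which(over)[1]
      abort(sprintf(
        "Peak %s:%s-%s extends past the chromosome end (%s bp).",
        x$chrom[i], format(x$start[i], scientific = FALSE),
        format(x$end[i], scientific = FALSE),
        format(lens[x$chrom[i]], scientific = FALSE)
      ))
    }
    chrom_levels <- genome$chrom
  }
  ord <- order(match(x$chrom, chrom_levels), x$start, x$end)
  x <- x[ord, , drop = FALSE]
  attr(x, "genome") <- genome
  attr(x, "label") <- label
  x
}

#' Read a BED3+ peak file
#'
#' Accepts BED3 to BED6 (extra columns beyond the sixth are ignored);
#' `track`, `browser` and `#` comment lines are skipped. Coordinates are
#' 0-based half-open. Errors name the offending file line.
#'
#' @inheritParams as_peaks
#' @param path Path to a BED file.
#' @return A sorted peak tibble (see [as_peaks()]); columns `name`/`score`
#'   are present when the file has them.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("track name=demo", "chrT\t100\t200\tp1\t50\t+"), f)
#' read_bed(f, chrom_sizes("chrT", 1000))
#' @export
read_bed <- function(path, genome = NULL, label = NULL,
                     on_unknown_chrom = c("error", "drop")) {
  lines <- readLines(path, warn = FALSE)
  is_header <- grepl("^(track|browser)\\b|^#", lines)
  keep <- nzchar(trimws(lines)) & !is_header
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0) {
    return(as_peaks(
      tibble(chrom = character(), start = numeric(), end = numeric()),
      genome = genome, label = label
    ))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    abort(sprintf("%s line %d: BED needs at least 3 columns.",
                  path, lineno[which(n_fields < 3)[1]]))
  }
  get_col <- function(i) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_,
           character(1))
  }
  chrom <- get_col(1)
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("%s line %d: invalid interval '%s'.", path, lineno[i], body[i]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (any(n_fields >= 4)) {
    nm <- get_col(4)
    nm[nm == "."] <- NA_character_
    out$name <- nm
  }
  if (any(n_fields >= 5)) {
    out$score <- suppressWarnings(as.numeric(get_col(5)))
  }
  as_peaks(out, genome = genome, label = label,
           on_unknown_chrom = match.arg(on_unknown_chrom))
}

#' Write a peak table as BED
#'
#' Emits BED3, or BED4 when the table has any peak names. The written file
#' round-trips: reading it back reproduces the coordinates and order exactly.
#'
#' @param peaks A peak tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  fmt <- function(x) sprintf("%.0f", x)
  has_names <- "name" %in% names(peaks) && any(!is.na(peaks$name))
  if (nrow(peaks) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (has_names) {
    nm <- peaks$name
    nm[is.na(nm)] <- "."
    out <- paste(peaks$chrom, fmt(peaks$start), fmt(peaks$end), nm, sep = "\t")
  } else {
    out <- paste(peaks$chrom, fmt(peaks$start), fmt(peaks$end), sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Peak-set label
#' @param peaks A peak tibble.
#' @return The label attribute, or `"peaks"` if unset.
#' @export
peak_label <- function(peaks) {
  attr(peaks, "label", exact = TRUE) %||% "peaks"
}

# Internal: error unless two peak sets are bound to compatible genomes.
# Returns the shared genome (possibly NULL when neither carries one).
check_same_genome <- function(a, b, genome = NULL) {
  ga <- attr(a, "genome", exact = TRUE)
  gb <- attr(b, "genome", exact = TRUE)
  if (!is.null(genome)) {
    return(validate_genome(genome))
  }
  if (!is.null(ga) && !is.null(gb) && !isTRUE(all.equal(ga, gb))) {
    abort("Peak sets are bound to different genomes.")
  }
  ga %||% gb
}

# Internal: split a peak table into per-chromosome coordinate lists
# (start, end, width, idx = row indices into the original table).
split_coords <- function(peaks) {
  idx <- split(seq_len(nrow(peaks)), peaks$chrom)
  lapply(idx, function(i) {
    list(start = peaks$start[i], end = peaks$end[i],
         width = peaks$end[i] - peaks$start[i], idx = i)
  })
}
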