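#' Demo genome for simulations
#'
#' Five 50-Mb chromosomes by default: small enough for seconds-scale runs,
#' sparse enough that chance overlap between a few thousand ~200-bp peaks is
#' rare.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (recycled).
#' @param prefix Chromosome name prefix.
#' @return A genome tibble (see [chrom_sizes()]).
#' @export
sim_genome <- function(n_chrom = 5, chrom_length = 5e7, prefix = "chr") {
  chrom_sizes(paste0(prefix, seq_len(n_chrom)),
              rep_len(chrom_length, n_chrom))
}

# Internal: peak widths. Fixed when `width` is given; otherwise lognormal
# with median exp(meanlog) (default ~200 bp, the average chromatin fragment
# size the generator emulates), truncated to [min_width, max_width] by
# redrawing.
sim_widths <- function(n, width = NULL, meanlog = log(200), sdlog = 0.35,
                       min_width = 50, max_width = 10000) {
  if (!is.null(width)) {
    return(rep_len(round(width), n))
  }
  w <- round(rlnorm(n, meanlog, sdlog))
  bad <- which(w < min_width | w > max_width)
  while (length(bad) > 0) {
    w[bad] <- round(rlnorm(length(bad), meanlog, sdlog))
    bad <- bad[w[bad] < min_width | w[bad] > max_width]
  }
  w
}

#' Generate anchor peaks placed independently on a genome
#'
#' Places `n` peaks with chromosomes chosen with probability proportional to
#' length, widths from a truncated lognormal (median ~200 bp by default, or a
#' fixed `width`), and starts uniform within the chromosome. Warns when the
#' requested density exceeds one peak per 10 kb, where chance overlap stops
#' being rare.
#'
#' @param genome Genome tibble.
#' @param n Number of peaks.
#' @param width Optional fixed width (bp); otherwise lognormal.
#' @param meanlog,sdlog,min_width,max_width Width distribution parameters.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param label Label for the peak set.
#' @return A sorted peak tibble bound to `genome`, with peak names.
#' @examples
#' sim_anchor_peaks(sim_genome(2, 1e6), n = 10, seed = 1)
#' @export
sim_anchor_peaks <- function(genome, n, width = NULL, meanlog = log(200),
                             sdlog = 0.35, min_width = 50, max_width = 10000,
                             seed = NULL, label = "anchors") {
  genome <- validate_genome(genome)
  if (!is.null(seed)) set.seed(seed)
  if (n > 0 && sum(genome$length) / n < 1e4) {
    warn("Peak density above 1 per 10 kb; chance overlap will be common.")
  }
  w <- sim_widths(n, width, meanlog, sdlog, min_width, max_width)
  if (any(w > max(genome$length))) {
    abort("A sampled width exceeds every chromosome length.")
  }
  ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  L <- genome$length[ci]
  if (any(w > L)) { # re-assign the rare peak wider than its chromosome
    for (i in which(w > L)) {
      ok <- which(genome$length >= w[i])
      ci[i] <- ok[sample.int(length(ok), 1)]
      L[i] <- genome$length[ci[i]]
    }
  }
  s <- random_starts(w, L)
  as_peaks(
    tibble(chrom = genome$chrom[ci], start = s, end = s + w,
           name = sprintf("%s_%05d", label, seq_len(max(n, 0)))[seq_len(n)]),
    genome = genome, label = label
  )
}

#' Generate query peaks with controlled colocalization to anchors
#'
#' Plants `round(rho * n)` peaks at anchors (anchor chosen uniformly, planted
#' midpoint = anchor midpoint + Normal(0, `offset_sd`), clamped to the
#' chromosome) and places the remaining peaks independently as in
#' [sim_anchor_peaks()]. The returned table carries a logical `planted`
#' column (the ground truth for parameter recovery) and attributes
#' `n_clamped` (planted peaks whose position had to be clamped at a
#' chromosome end) and `label`.
#'
#' @param anchors Anchor peak tibble (non-empty when `rho > 0`).
#' @param genome Genome tibble.
#' @param n Number of query peaks.
#' @param rho Fraction of query peaks planted at anchors, in `[0, 1]`.
#' @param offset_sd SD (bp) of the planted-midpoint offset from the anchor
#'   midpoint.
#' @param match_widths If `TRUE`, planted peaks copy their anchor's width
#'   instead of drawing from the width distribution.
#' @inheritParams sim_anchor_peaks
#' @return A sorted peak tibble with columns `chrom`, `start`, `end`, `name`,
#'   `planted`.
#' @export
sim_query_peaks <- function(anchors, genome, n, rho = 0.8, offset_sd = 100,
                            width = NULL, meanlog = log(200), sdlog = 0.35,
                            min_width = 50, max_width = 10000,
                            match_widths = FALSE, seed = NULL,
                            label = "query") {
  genome <- validate_genome(genome)
  if (rho < 0 || rho > 1) abort("`rho` must be in [0, 1].")
  if (rho > 0 && nrow(anchors) == 0) {
    abort("`rho` > 0 requires a non-empty anchor set.")
  }
  if (!is.null(seed)) set.seed(seed)
  n_plant <- round(rho * n)
  lens <- genome_lengths(genome)

  planted <- NULL
  n_clamped <- 0L
  if (n_plant > 0) {
    ai <- sample.int(nrow(anchors), n_plant, replace = TRUE)
    amid <- (anchors$start[ai] + anchors$end[ai]) %/% 2
    w <- if (match_widths) {
      anchors$end[ai] - anchors$start[ai]
    } else {
      sim_widths(n_plant, width, meanlog, sdlog, min_width, max_width)
    }
    mid <- amid + round(rnorm(n_plant, 0, offset_sd))
    s <- mid - w %/% 2
    L <- lens[anchors$chrom[ai]]
    s_cl <- pmin(pmax(s, 0), L - w)
    n_clamped <- sum(s_cl != s)
    planted <- tibble(chrom = anchors$chrom[ai], start = s_cl, end = s_cl + w,
                      planted = TRUE)
  }
  free <- NULL
  if (n - n_plant > 0) {
    bg <- sim_anchor_peaks(genome, n - n_plant, width, meanlog, sdlog,
                           min_width, max_width, seed = NULL, label = label)
    free <- tibble(chrom = bg$chrom, start = bg$start, end = bg$end,
                   planted = FALSE)
  }
  out <- dplyr::bind_rows(planted, free)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  planted = logical())
  }
  out$name <- sprintf("%s_%05d", label, seq_len(nrow(out)))
  out <- as_peaks(out, genome = genome, label = label)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Generate a replication-origin scenario with known truth
#'
#' Places `n_origins` Mcm (licensed-origin) peaks independently on the
#' genome, marks `round(fraction_active * n_origins)` of them (chosen at
#' random) as truly active, and plants one PCNA peak on each truly active
#' origin with the origin's width and a midpoint offset of SD `offset_sd`.
#' Optional background PCNA peaks are placed independently. The Mcm table
#' carries the ground truth in its `truly_active` column.
#'
#' @param genome Genome tibble.
#' @param n_origins Number of licensed origins (>= 1).
#' @param fraction_active Fraction of origins that fire, in `[0, 1]`.
#' @param offset_sd SD (bp) of the planted PCNA midpoint offset.
#' @param n_background Number of additional independently placed PCNA peaks.
#' @inheritParams sim_anchor_peaks
#' @return A list with peak tibbles `mcm` (with `truly_active`) and `pcna`.
#' @export
sim_origin_scenario <- function(genome, n_origins, fraction_active = 0.6,
                                offset_sd = 100, n_background = 0,
                                width = NULL, meanlog = log(200), sdlog = 0.35,
                                seed = NULL) {
  genome <- validate_genome(genome)
  if (n_origins < 1) abort("`n_origins` must be >= 1.")
  if (fraction_active < 0 || fraction_active > 1) {
    abort("`fraction_active` must be in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)
  mcm <- sim_anchor_peaks(genome, n_origins, width, meanlog, sdlog,
                          seed = NULL, label = "mcm")
  n_active <- round(fraction_active * n_origins)
  mcm$truly_active <- FALSE
  mcm$truly_active[sample.int(n_origins, n_active)] <- TRUE

  # exactly one width-matched PCNA peak per truly active origin
  active <- mcm[mcm$truly_active, , drop = FALSE]
  planted <- NULL
  if (n_active > 0) {
    w <- active$end - active$start
    mid <- (active$start + active$end) %/% 2 + round(rnorm(n_active, 0, offset_sd))
    s <- mid - w %/% 2
    L <- genome_lengths(genome)[active$chrom]
    s <- pmin(pmax(s, 0), L - w)
    planted <- tibble(chrom = active$chrom, start = s, end = s + w)
  }
  background <- NULL
  if (n_background > 0) {
    bg <- sim_anchor_peaks(genome, n_background, width, meanlog, sdlog,
                           seed = NULL, label = "pcna")
    background <- tibble(chrom = bg$chrom, start = bg$start, end = bg$end)
  }
  pcna <- dplyr::bind_rows(planted, background)
  if (is.null(pcna) || nrow(pcna) == 0) {
    pcna <- tibble(chrom = character(), start = numeric(), end = numeric())
  }
  pcna$name <- sprintf("pcna_%05d", seq_len(nrow(pcna)))
  pcna <- as_peaks(pcna, genome = genome, label = "pcna")
  mcm <- as_peaks(mcm, genome = genome, label = "mcm")
  list(mcm = mcm, pcna = pcna)
}

#' Plant a coverage query on classified origins
#'
#' Builds a query factor that covers prescribed fractions of the active and
#' dormant origin classes (e.g. 97% and 50%), by planting width-matched peaks
#' with a small midpoint offset on a random subset of each class. Used to
#' validate the coverage bookkeeping of [class_coverage()].
#'
#' @param classes An `origin_classes` object.
#' @param genome Genome tibble.
#' @param frac_active,frac_dormant Fractions of each class to cover.
#' @param offset_sd SD (bp) of the planted midpoint offset; the default 25 bp
#'   keeps planted peaks reliably above the reciprocal 25% criterion so the
#'   recovered fractions measure the bookkeeping, not offset noise.
#' @inheritParams sim_anchor_peaks
#' @return A peak tibble covering the requested class fractions.
#' @export
sim_coverage_query <- function(classes, genome, frac_active = 0.97,
                               frac_dormant = 0.5, offset_sd = 25,
                               seed = NULL, label = "coverage_query") {
  stopifnot(inherits(classes, "origin_classes"))
  genome <- validate_genome(genome)
  if (!is.null(seed)) set.seed(seed)
  plant_on <- function(class_peaks, frac) {
    n <- round(frac * nrow(class_peaks))
    if (n == 0) return(NULL)
    sel <- sample.int(nrow(class_peaks), n)
    w <- class_peaks$end[sel] - class_peaks$start[sel]
    mid <- (class_peaks$start[sel] + class_peaks$end[sel]) %/% 2 +
      round(rnorm(n, 0, offset_sd))
    s <- mid - w %/% 2
    L <- genome_lengths(genome)[class_peaks$chrom[sel]]
    s <- pmin(pmax(s, 0), L - w)
    tibble(chrom = class_peaks$chrom[sel], start = s, end = s + w)
  }
  out <- dplyr::bind_rows(
    plant_on(classes$active, frac_active),
    plant_on(classes$dormant, frac_dormant)
  )
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric())
  }
  out$name <- sprintf("%s_%05d", label, seq_len(nrow(out)))
  as_peaks(out, genome = genome, label = label)
}
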