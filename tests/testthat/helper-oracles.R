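# Independent brute-force oracles and small random-instance generators used
# across the suite. These deliberately avoid the package's sweep/sort
# machinery: overlap counting is all-pairs via outer(), nearest-distance is a
# per-query scan.

brute_count_overlapped <- function(query, reference, mode, threshold) {
  nq <- nrow(query)
  nr <- nrow(reference)
  if (nq == 0 || nr == 0) {
    return(c(query_overlapped = 0L, reference_overlapped = 0L, pairs = 0L))
  }
  I <- outer(query$end, reference$end, pmin) -
    outer(query$start, reference$start, pmax)
  I[I < 0] <- 0
  I[outer(query$chrom, reference$chrom, "!=")] <- 0
  fq <- I / (query$end - query$start)
  fr <- sweep(I, 2, reference$end - reference$start, "/")
  ok <- switch(mode,
    reciprocal = fq >= threshold & fr >= threshold,
    query_fraction = fq >= threshold,
    reference_fraction = fr >= threshold
  )
  ok <- ok & I > 0
  c(query_overlapped = sum(rowSums(ok) > 0),
    reference_overlapped = sum(colSums(ok) > 0),
    pairs = sum(ok))
}

# Nearest same-chromosome reference by midpoint; ties toward the smaller
# reference start, then the smaller index.
brute_nearest <- function(query, reference) {
  qm <- (query$start + query$end) %/% 2
  rm_ <- (reference$start + reference$end) %/% 2
  rows <- lapply(seq_len(nrow(query)), function(i) {
    cand <- which(reference$chrom == query$chrom[i])
    if (length(cand) == 0) return(NULL)
    d <- rm_[cand] - qm[i]
    best <- cand[abs(d) == min(abs(d))]
    best <- best[order(reference$start[best], best)][1]
    data.frame(query_idx = i, ref_idx = best,
               signed_distance = rm_[best] - qm[i])
  })
  do.call(rbind, rows)
}

# Random small peak set on a toy genome (no genome binding by default so
# mismatch tests can attach their own).
toy_genome <- function() chrom_sizes(c("chrA", "chrB"), c(50000, 80000))

rand_peaks <- function(n, genome = toy_genome(), max_width = 2000) {
  if (n == 0) {
    return(as_peaks(
      data.frame(chrom = character(), start = numeric(), end = numeric()),
      genome
    ))
  }
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s <- floor(runif(n) * (genome$length[ci] - w))
  as_peaks(data.frame(chrom = genome$chrom[ci], start = s, end = s + w), genome)
}

peak_row <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end)
}
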