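test_that("overlap fractions follow interval arithmetic", {
  expect_equal(
    overlap_fraction(peak_row("c", 100, 200), peak_row("c", 100, 200)),
    tibble::tibble(intersection = 100, frac_a = 1, frac_b = 1)
  )
  fr <- overlap_fraction(peak_row("c", 100, 200), peak_row("c", 150, 260))
  expect_equal(fr$intersection, 50)
  expect_equal(fr$frac_a, 0.50)
  expect_equal(fr$frac_b, 50 / 110)

  fr2 <- overlap_fraction(peak_row("c", 0, 100), peak_row("c", 95, 300))
  expect_equal(fr2$frac_a, 0.05)
  expect_equal(fr2$frac_b, 5 / 205)

  # different chromosomes never intersect
  expect_equal(
    overlap_fraction(peak_row("c1", 0, 100), peak_row("c2", 0, 100))$intersection, 0
  )
})

test_that("overlap_fraction is symmetric with fractions exchanged", {
  set.seed(13)
  for (i in 1:200) {
    a <- peak_row("c", s1 <- sample(0:1000, 1), s1 + sample(1:500, 1))
    b <- peak_row(sample(c("c", "d"), 1), s2 <- sample(0:1000, 1), s2 + sample(1:500, 1))
    ab <- overlap_fraction(a, b)
    ba <- overlap_fraction(b, a)
    expect_identical(ab$frac_a, ba$frac_b)
    expect_identical(ab$frac_b, ba$frac_a)
    expect_true(all(ab$frac_a >= 0 & ab$frac_a <= 1))
  }
})

test_that("the 25% span criterion is inclusive and mode-dependent", {
  a <- peak_row("c", 100, 200)
  b <- peak_row("c", 150, 260)
  for (m in c("reciprocal", "query_fraction", "reference_fraction")) {
    expect_true(peaks_overlap(a, a, mode = m))
  }
  expect_true(peaks_overlap(a, b, mode = "reciprocal")) # 0.50 and 0.4545
  expect_false(peaks_overlap(peak_row("c", 0, 100), peak_row("c", 95, 300)))
  expect_false(peaks_overlap(peak_row("c", 0, 100), peak_row("c", 95, 300),
                             mode = "query_fraction"))

  # boundary: exactly 25% of both spans counts as overlapping
  expect_true(peaks_overlap(peak_row("c", 0, 100), peak_row("c", 75, 175)))

  # one-sided mode is asymmetric on width-unequal pairs
  wide <- peak_row("c", 0, 1000)
  narrow <- peak_row("c", 0, 100)
  expect_true(peaks_overlap(narrow, wide, mode = "query_fraction"))
  expect_false(peaks_overlap(wide, narrow, mode = "query_fraction"))

  expect_error(peaks_overlap(a, b, threshold = 0), "threshold")
  expect_error(peaks_overlap(a, b, threshold = 1.5), "threshold")
})

test_that("count_overlapped handles identity and disjoint-chromosome cases", {
  g <- toy_genome()
  set.seed(3)
  ps <- rand_peaks(20, g)
  self <- count_overlapped(ps, ps)
  expect_equal(self$n_query_overlapped, nrow(ps))
  expect_equal(self$n_reference_overlapped, nrow(ps))
  expect_gte(self$n_pairs, nrow(ps))

  qa <- as_peaks(peak_row("chrA", c(0, 100), c(50, 200)), g)
  rb <- as_peaks(peak_row("chrB", c(0, 100), c(50, 200)), g)
  res <- count_overlapped(qa, rb)
  expect_equal(res$n_query_overlapped, 0)
  expect_equal(res$n_pairs, 0)
})

test_that("the sweep matches the all-pairs brute force on random instances", {
  set.seed(101)
  modes <- c("reciprocal", "query_fraction", "reference_fraction")
  for (i in 1:200) {
    q <- rand_peaks(sample(0:50, 1))
    r <- rand_peaks(sample(0:50, 1))
    m <- sample(modes, 1)
    t <- runif(1, 0.01, 1)
    got <- count_overlapped(q, r, mode = m, threshold = t)
    want <- brute_count_overlapped(q, r, m, t)
    expect_equal(got$n_query_overlapped, unname(want["query_overlapped"]))
    expect_equal(got$n_reference_overlapped, unname(want["reference_overlapped"]))
    expect_equal(got$n_pairs, unname(want["pairs"]))
  }
})

test_that("lowering the threshold never decreases any overlap count", {
  set.seed(23)
  q <- rand_peaks(40)
  r <- rand_peaks(40)
  for (m in c("reciprocal", "query_fraction")) {
    prev <- NULL
    for (t in c(1, 0.75, 0.5, 0.25, 0.1, 0.01)) {
      cur <- count_overlapped(q, r, mode = m, threshold = t)
      if (!is.null(prev)) {
        expect_gte(cur$n_query_overlapped, prev$n_query_overlapped)
        expect_gte(cur$n_reference_overlapped, prev$n_reference_overlapped)
        expect_gte(cur$n_pairs, prev$n_pairs)
      }
      prev <- cur
    }
  }
})

test_that("peak sets bound to different genomes are refused", {
  g1 <- chrom_sizes("chrA", 1000)
  g2 <- chrom_sizes("chrA", 2000)
  a <- as_peaks(peak_row("chrA", 0, 100), g1)
  b <- as_peaks(peak_row("chrA", 0, 100), g2)
  expect_error(count_overlapped(a, b), "different genomes")
})
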