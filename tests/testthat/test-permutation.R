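test_that("randomization preserves counts and widths and stays in bounds", {
  g <- toy_genome()
  set.seed(17)
  ps <- rand_peaks(60, g)
  for (i in 1:50) {
    rd <- randomize_peaks(ps, g)
    expect_equal(table(rd$chrom), table(ps$chrom))
    for (ch in unique(ps$chrom)) {
      expect_equal(
        sort((rd$end - rd$start)[rd$chrom == ch]),
        sort((ps$end - ps$start)[ps$chrom == ch])
      )
    }
    lens <- stats::setNames(g$length, g$chrom)
    expect_true(all(rd$start >= 0))
    expect_true(all(rd$end <= lens[rd$chrom]))
  }
})

test_that("a peak as wide as its chromosome is forced to start 0; wider errors", {
  g <- chrom_sizes("chrT", 1000)
  full <- as_peaks(peak_row("chrT", 0, 1000), g)
  set.seed(1)
  rd <- randomize_peaks(full, g)
  expect_equal(rd$start, 0)
  expect_equal(rd$end, 1000)

  g_small <- chrom_sizes("chrT", 500)
  wide <- as_peaks(peak_row("chrT", 0, 400), g_small)
  wide$end <- 600 # widen past the chromosome after construction
  expect_error(randomize_peaks(wide, g_small), "wider than its chromosome")

  # empty set passes through
  expect_equal(nrow(randomize_peaks(rand_peaks(0), toy_genome())), 0)
})

test_that("randomized starts are uniform on [0, L - w]", {
  # 10,000 width-100 peaks on a 1000 bp chromosome: mean start should be
  # within 3 standard errors of the uniform mean 450
  g <- chrom_sizes("chrT", 1000)
  ps <- as_peaks(peak_row("chrT", rep(0, 10000), rep(100, 10000)), g)
  set.seed(99)
  rd <- randomize_peaks(ps, g)
  se <- sqrt((901^2 - 1) / 12 / 10000)
  expect_lt(abs(mean(rd$start) - 450), 3 * se)
  expect_gte(min(rd$start), 0)
  expect_lte(max(rd$start), 900)
})

test_that("rejection mode yields mutually disjoint randomized peaks", {
  g <- chrom_sizes("chrT", 100000)
  ps <- as_peaks(peak_row("chrT", seq(0, 900, by = 100), seq(50, 950, by = 100)), g)
  set.seed(4)
  rd <- randomize_peaks(ps, g, no_self_overlap = TRUE)
  o <- order(rd$start)
  expect_true(all(rd$start[o][-1] >= head(rd$end[o], -1)))
})

test_that("an empty query gives the degenerate p-value 1", {
  g <- toy_genome()
  q <- rand_peaks(0, g)
  set.seed(2)
  r <- rand_peaks(10, g)
  pt <- permutation_test(q, r, g, n_perm = 50, seed = 5)
  expect_equal(pt$observed, 0)
  expect_true(all(pt$null_stats == 0))
  expect_equal(pt$n_exceed_tied, 50)
  expect_equal(pt$p_add_one, 1)
})

test_that("perfect colocation on a sparse genome gives the minimal p-value", {
  g <- chrom_sizes("chr1", 5e7)
  anchors <- sim_anchor_peaks(g, 500, width = 500, seed = 8)
  pt <- permutation_test(anchors, anchors, g, n_perm = 199, seed = 9)
  expect_equal(pt$observed, 500)
  expect_equal(pt$n_exceed_strict, 0)
  expect_equal(pt$p_add_one, 1 / 200)
  expect_equal(pt$p_bound, "<0.00502513")
  # the null mean is close to the Poisson-style chance expectation:
  # each of 500 shuffled width-500 peaks can pair with 500 anchors within
  # ~|mid offset| <= 375 bp (reciprocal 25% of equal widths), so
  # E[statistic] is of order 500 * 500 * 750 / 5e7 ~ 3.75; far below 500
  expect_lt(mean(pt$null_stats), 20)
})

test_that("identical seeds reproduce the null sequence bit for bit", {
  g <- toy_genome()
  set.seed(31)
  q <- rand_peaks(30, g)
  r <- rand_peaks(30, g)
  a <- permutation_test(q, r, g, n_perm = 100, seed = 123)
  b <- permutation_test(q, r, g, n_perm = 100, seed = 123)
  expect_identical(a$null_stats, b$null_stats)
  expect_identical(glance(a), glance(b))
  c <- permutation_test(q, r, g, n_perm = 100, seed = 124)
  expect_false(identical(a$null_stats, c$null_stats))
})

test_that("either set can be designated for shuffling", {
  g <- chrom_sizes("chr1", 1e6)
  anc <- sim_anchor_peaks(g, 50, seed = 3)
  qry <- sim_query_peaks(anc, g, 50, rho = 1, offset_sd = 0,
                         match_widths = TRUE, seed = 4)
  pq <- permutation_test(qry, anc, g, n_perm = 99, seed = 1, shuffle = "query")
  pr <- permutation_test(qry, anc, g, n_perm = 99, seed = 1, shuffle = "reference")
  expect_equal(pq$observed, pr$observed)
  expect_equal(pq$observed, 50)
  expect_equal(pq$n_exceed_strict, 0)
  expect_error(permutation_test(qry, anc, g, n_perm = 0), "n_perm")
})

test_that("p_add_one stays within its theoretical range", {
  g <- toy_genome()
  set.seed(71)
  for (i in 1:10) {
    q <- rand_peaks(sample(1:20, 1), g)
    r <- rand_peaks(sample(1:20, 1), g)
    pt <- permutation_test(q, r, g, n_perm = 19, seed = i)
    expect_gte(pt$p_add_one, 1 / 20)
    expect_lte(pt$p_add_one, 1)
    expect_lte(pt$n_exceed_strict, pt$n_exceed_tied)
  }
})
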