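test_that("generators are deterministic under a fixed seed", {
  g <- sim_genome(3, 1e7)
  a1 <- sim_anchor_peaks(g, 200, seed = 11)
  a2 <- sim_anchor_peaks(g, 200, seed = 11)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  q1 <- sim_query_peaks(a1, g, 200, rho = 0.5, seed = 12)
  q2 <- sim_query_peaks(a1, g, 200, rho = 0.5, seed = 12)
  expect_identical(as.data.frame(q1), as.data.frame(q2))
  s1 <- sim_origin_scenario(g, 100, seed = 13)
  s2 <- sim_origin_scenario(g, 100, seed = 13)
  expect_identical(as.data.frame(s1$pcna), as.data.frame(s2$pcna))
})

test_that("all generated peaks satisfy genome bounds and width truncation", {
  g <- sim_genome(2, 2e6)
  lens <- stats::setNames(g$length, g$chrom)
  set.seed(2)
  for (i in 1:5) {
    a <- sim_anchor_peaks(g, 300)
    q <- sim_query_peaks(a, g, 300, rho = 0.7, offset_sd = 200)
    for (ps in list(a, q)) {
      expect_true(all(ps$start >= 0))
      expect_true(all(ps$end <= lens[ps$chrom]))
      w <- ps$end - ps$start
      expect_true(all(w >= 50 & w <= 10000))
    }
  }
  expect_equal(nrow(sim_anchor_peaks(g, 0)), 0)
})

test_that("independent peaks land on chromosomes proportionally to length", {
  g <- chrom_sizes(c("small", "big"), c(1e7, 4e7))
  a <- suppressWarnings(sim_anchor_peaks(g, 10000, seed = 19))
  n_small <- sum(a$chrom == "small")
  bounds <- stats::qbinom(c(0.005, 0.995), 10000, 0.2)
  expect_gte(n_small, bounds[1])
  expect_lte(n_small, bounds[2])
})

test_that("rho = 1 with zero offset and matched widths forces full overlap", {
  g <- sim_genome(2, 1e7)
  a <- sim_anchor_peaks(g, 150, seed = 29)
  q <- sim_query_peaks(a, g, 150, rho = 1, offset_sd = 0,
                       match_widths = TRUE, seed = 30)
  expect_true(all(q$planted))
  ov <- count_overlapped(q, a, g)
  expect_equal(ov$n_query_overlapped, 150)
  # every planted peak coincides exactly with its anchor
  expect_true(all(ov$matched$frac_query[ov$matched$frac_ref == 1] <= 1))
})

test_that("planted colocalization fraction is recovered from overlap counts", {
  g <- sim_genome()
  rho <- 0.8
  a <- sim_anchor_peaks(g, 1000, seed = 31)
  q <- sim_query_peaks(a, g, 2000, rho = rho, offset_sd = 0,
                       match_widths = TRUE, seed = 32)
  obs <- count_overlapped(q, a, g)$n_query_overlapped / 2000
  # background rate estimated from an independent rho = 0 draw
  q0 <- sim_query_peaks(a, g, 2000, rho = 0, seed = 33)
  bg <- count_overlapped(q0, a, g)$n_query_overlapped / 2000
  expect_lt(abs((obs - bg) - rho), 0.03)
})

test_that("planted peaks are clamped rarely and the count is reported", {
  g <- sim_genome()
  a <- sim_anchor_peaks(g, 1000, seed = 41)
  q <- sim_query_peaks(a, g, 1000, rho = 0.8, offset_sd = 100, seed = 42)
  expect_lt(attr(q, "n_clamped"), 0.01 * 1000)
})

test_that("degenerate generator inputs are rejected", {
  g <- sim_genome(1, 1e6)
  a <- sim_anchor_peaks(g, 10, seed = 1)
  expect_error(sim_query_peaks(a[0, ], g, 10, rho = 0.5), "non-empty anchor")
  expect_error(sim_query_peaks(a, g, 10, rho = 1.5), "rho")
  expect_error(sim_origin_scenario(g, 0), "n_origins")
  expect_warning(sim_anchor_peaks(chrom_sizes("c", 1e5), 100, seed = 2),
                 "density")
})
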