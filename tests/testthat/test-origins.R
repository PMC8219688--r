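test_that("origin classification partitions the licensed set exactly", {
  g <- chrom_sizes("chrT", 2000)
  mcm <- as_peaks(peak_row("chrT", c(0, 500, 900), c(200, 700, 1100)), g)
  pcna <- as_peaks(peak_row("chrT", 100, 300), g)
  # intersection with the first Mcm peak is 100 bp: half of both spans
  cl <- classify_origins(mcm, pcna, g)
  expect_equal(cl$n_active, 1)
  expect_equal(cl$n_dormant, 2)
  expect_equal(cl$active$start, 0)

  # no PCNA: everything dormant; PCNA identical to Mcm: everything active
  empty <- as_peaks(peak_row(character(), numeric(), numeric()), g)
  expect_equal(classify_origins(mcm, empty, g)$n_dormant, 3)
  expect_equal(classify_origins(mcm, mcm, g)$n_active, 3)
})

test_that("partition invariant holds on random inputs including duplicates", {
  set.seed(37)
  g <- toy_genome()
  for (i in 1:25) {
    mcm <- rand_peaks(sample(1:40, 1), g)
    mcm <- as_peaks(mcm[sample(seq_len(nrow(mcm)), nrow(mcm), replace = TRUE), ], g)
    pcna <- rand_peaks(sample(0:40, 1), g)
    cl <- classify_origins(mcm, pcna, g)
    expect_equal(cl$n_active + cl$n_dormant, nrow(mcm))
    combined <- dplyr::bind_rows(cl$active, cl$dormant)
    combined <- combined[order(combined$chrom, combined$start, combined$end), ]
    expect_equal(combined$start, mcm$start)
    expect_equal(combined$end, mcm$end)
  }
})

test_that("classification is invariant under re-sorting of the inputs", {
  set.seed(53)
  g <- toy_genome()
  mcm <- rand_peaks(30, g)
  pcna <- rand_peaks(30, g)
  shuf <- as_peaks(mcm[sample(nrow(mcm)), ], g)
  a <- classify_origins(mcm, pcna, g)
  b <- classify_origins(shuf, pcna, g)
  expect_equal(a$n_active, b$n_active)
  expect_equal(a$active$start, b$active$start)
})

test_that("class coverage counts origins touched by a query factor", {
  g <- chrom_sizes("chrT", 10000)
  active <- as_peaks(peak_row("chrT", c(1000, 5000), c(1200, 5200)), g)
  q1 <- as_peaks(peak_row("chrT", 1000, 1200), g) # covers one of two
  cov <- class_coverage(q1, active, "active", g)
  expect_equal(cov$n_covered, 1)
  expect_equal(cov$fraction_covered, 0.5)

  # identity coverage
  expect_equal(class_coverage(active, active, "active", g)$fraction_covered, 1)

  # empty class is flagged, not an error
  empty <- as_peaks(peak_row(character(), numeric(), numeric()), g)
  cov0 <- class_coverage(q1, empty, "none", g)
  expect_equal(cov0$fraction_covered, 0)
  expect_true(cov0$empty_class)
})

test_that("coverage of the union is the count-weighted mean of class coverages", {
  set.seed(61)
  g <- toy_genome()
  for (i in 1:20) {
    mcm <- rand_peaks(sample(2:40, 1), g)
    pcna <- rand_peaks(sample(0:40, 1), g)
    qry <- rand_peaks(sample(1:40, 1), g)
    cl <- classify_origins(mcm, pcna, g)
    cov <- origin_coverage(qry, cl, g)
    whole <- class_coverage(qry, mcm, "all", g)
    expect_equal(
      whole$n_covered,
      sum(cov$n_covered)
    )
    if (whole$n_class > 0) {
      expect_equal(
        whole$fraction_covered,
        sum(cov$fraction_covered * cov$n_class) / whole$n_class
      )
    }
  }
})

test_that("classifier recovery on planted scenarios matches the analytic expectation", {
  # With width-matched planting and a Normal(0, sd) midpoint offset, a truly
  # active origin is recovered iff |offset| <= 0.75 w (reciprocal 25% rule),
  # so expected accuracy = (1 - f) + f * E[2 Phi(0.75 w / sd) - 1].
  gen <- sim_genome()
  set.seed(773)
  w_mc <- pmin(pmax(round(rlnorm(5e5, log(200), 0.35)), 50), 10000)
  expected_acc <- 0.4 + 0.6 * mean(2 * stats::pnorm(0.75 * w_mc / 100) - 1)

  sc <- sim_origin_scenario(gen, 1000, fraction_active = 0.6,
                            offset_sd = 100, seed = 101)
  cl <- classify_origins(sc$mcm, sc$pcna, gen)
  pred_active <- sc$mcm$name %in% cl$active$name
  acc <- mean(pred_active == sc$mcm$truly_active)
  expect_lt(abs(acc - expected_acc), 0.025)

  # forced edges: zero offset recovers the truth exactly
  sc1 <- sim_origin_scenario(gen, 200, fraction_active = 1, offset_sd = 0, seed = 5)
  expect_equal(classify_origins(sc1$mcm, sc1$pcna, gen)$n_active, 200)
  sc0 <- sim_origin_scenario(gen, 200, fraction_active = 0, offset_sd = 0, seed = 6)
  expect_equal(classify_origins(sc0$mcm, sc0$pcna, gen)$n_dormant, 200)
})
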