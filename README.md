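# peakcoloc

Colocalization analysis of ChIP-seq peak sets with width- and
count-preserving randomization nulls.

## What problem this solves

Given two ChIP-seq peak sets — say PCNA (the replication sliding clamp) and
gamma-tubulin on S-phase chromatin — how strong is the evidence that the two
factors occupy the *same* genomic regions? Raw overlap counts mean little
because dense interval sets overlap by chance. peakcoloc provides, for
people analyzing peak-level ChIP-seq output:

* a **span-overlap criterion**: peaks overlap when their shared span covers
  at least a fraction *t* (default 25%) of both peak widths (reciprocal
  mode) or of one side only (one-sided modes), compared inclusively;
* **nearest-peak distance distributions**: signed midpoint distances from
  each query peak to its closest same-chromosome reference peak;
* an **empirical permutation test**: the reference set is re-placed at
  random positions *within its own chromosomes* `n_perm` times, keeping the
  per-chromosome peak counts and the multiset of peak widths exactly
  unchanged. With observed statistic *T*(obs) and null statistics *T*(1..N),
  the reported p-value is the add-one estimator

  p = (1 + #{ i : T(i) >= T(obs) }) / (N + 1),

  alongside the strict exceedance count and the bound p < 1/N when no
  permutation reaches the observed value;
* a **distance-narrowness report**: observed IQR versus randomized IQRs
  (ratio to the median null) plus a Kolmogorov–Smirnov statistic on
  absolute distances;
* a **replication-origin classifier**: Mcm peaks that overlap a PCNA peak
  (reciprocal 25%) are *active* origins, the rest *dormant*, with coverage
  reports for any third factor over each class;
* a **2×2 cohort chi-squared** (e.g. gamma-tubulin vs PCNA
  immunohistochemistry staining) with odds ratio and per-group proportions;
* a **synthetic peak generator** with controlled colocalization fraction,
  offset noise, and planted ground truth, so every statistical claim is
  testable without downloading data, and a `coloc_run()` pipeline that
  writes tabular reports with a checksum manifest.

Peak sets and genomes are plain tibbles (BED and chrom.sizes readers
included); results are S3 objects with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(peakcoloc)

genome <- sim_genome(5, 5e7)                      # 5 chromosomes x 50 Mb
tubg   <- sim_anchor_peaks(genome, 1000, seed = 101, label = "gamma_tubulin")
pcna   <- sim_query_peaks(tubg, genome, 1200, rho = 0.8, offset_sd = 100,
                          seed = 102, label = "PCNA")

count_overlapped(pcna, tubg, genome)
#> Peak overlap (reciprocal, threshold 0.25): PCNA vs gamma_tubulin
#>   query overlapped:     785 / 1200
#>   reference overlapped: 543 / 1000
#>   qualifying pairs:     789

permutation_test(pcna, tubg, genome, n_perm = 2000, seed = 103)
#> Colocalization permutation test: PCNA vs gamma_tubulin (reference shuffled)
#>   statistic (query_overlapped): observed = 785
#>   randomizations: 2000 (seed 103), null mean 1.37, max 8
#>   exceedances: strict 0, tied 0
#>   empirical p (add-one) = 0.0004998  [no strict exceedance: p <0.0005]

distance_narrowness(pcna, tubg, genome, seed = 104)
#> Distance-distribution narrowness: PCNA vs gamma_tubulin
#>   observed IQR: 169 bp; median null IQR: 172486 bp; ratio 0.0010
#>   KS statistic (observed vs pooled null): 0.798
```

Reading the output: 785 of the 1200 PCNA peaks overlap a gamma-tubulin peak
(80% were planted at anchors; the ones lost to the 100 bp offset noise or
placed independently do not qualify), while random placement of the
reference set yields at most 8 overlapped peaks in 2000 tries — the
observed count is never reached, so the empirical p-value is the estimator
floor 1/2001 ≈ 0.0005. The observed nearest-distance IQR (169 bp) is three
orders of magnitude tighter than the randomized one.

Origin classification on a planted scenario:

```r
sc <- sim_origin_scenario(genome, 1000, fraction_active = 0.6,
                          offset_sd = 100, seed = 105)
classify_origins(sc$mcm, sc$pcna, genome)
#> Origin classification (mcm vs pcna, reciprocal threshold 0.25):
#>   active:  498 / 1000 (49.8%)
#>   dormant: 502 / 1000
```

(600 origins were planted as active; ~100 fall below the reciprocal 25%
criterion at offset SD 100 bp — the methods vignette derives this expected
recovery in closed form.)

Cohort association on the packaged ovarian-cancer counts:

```r
tab <- read_cohort_counts(system.file("extdata", "ovarian_cohort_counts.csv",
                                      package = "peakcoloc"))
chi2_2x2(tab)
#> 2x2 chi-squared association test
#>           pcna_high pcna_low
#> low_TUBG         38       19
#> high_TUBG        79       11
#>   X-squared = 9.5752, df = 1, p = 0.001972
#>   odds ratio = 0.2785
```

File-driven analyses use the same functions via `read_chrom_sizes()` and
`read_bed()`, or the orchestrated `coloc_run(coloc_config(...), out_dir)`,
which writes per-stage TSV/JSON reports, the resolved configuration, and a
`manifest.tsv` of MD5 checksums (reruns with the same seed are
byte-identical).

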