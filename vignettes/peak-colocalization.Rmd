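---
title: "Methods: peak colocalization, randomization nulls, and origin classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak colocalization, randomization nulls, and origin classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcoloc)
```

## The question the package answers

ChIP-seq yields, for each chromatin-associated factor, a set of *peaks*:
genomic intervals where the factor is enriched. A recurring question is
whether two factors bind the *same* places — for instance, whether the
replication sliding clamp PCNA is loaded where gamma-tubulin sits on
chromatin, or whether a licensed replication origin (an Mcm helicase peak)
has actually fired (acquired a PCNA peak). Raw overlap counts are
uninterpretable on their own, because two dense peak sets overlap by chance;
the package therefore pairs every overlap statistic with an explicit
randomization null.

peakcoloc works on plain tibbles: a genome is a `chrom`/`length` table
(`chrom_sizes()`, `read_chrom_sizes()`), a peak set is a
`chrom`/`start`/`end` table in 0-based half-open BED coordinates
(`read_bed()`, `as_peaks()`). All coordinates are integers in bp.

## The span-overlap criterion

Two peaks on the same chromosome share a span of length
$I = \max(0, \min(e_1, e_2) - \max(s_1, s_2))$. The package calls a pair
overlapping when $I$ covers at least a threshold fraction $t$ of a peak's
width, with three modes:

* `reciprocal` (default): $I \ge t\,w_1$ **and** $I \ge t\,w_2$;
* `query_fraction`: $I \ge t\,w_{\mathrm{query}}$ only;
* `reference_fraction`: $I \ge t\,w_{\mathrm{reference}}$ only.

The default is $t = 0.25$ and reciprocal mode. Both conventions circulate in
the field — "at least 25% of its span" reads one-sided, "at least 25% for
both peaks" reads reciprocal — so both are first-class options rather than
one being silently imposed; the reciprocal form is the default because the
active-origin definition below explicitly requires the criterion for both
peaks. The comparison is inclusive (`>=`): a pair at exactly 25% counts.
Coordinates being half-open integers, all fractions are exact rationals and
no floating-point tolerance is needed at the threshold.

`count_overlapped()` applies the criterion set-versus-set. A query peak is
*overlapped* when at least one reference peak qualifies; the reference
direction and the number of qualifying pairs are kept alongside. Matching is
a per-chromosome sweep: references sorted by start, a `findInterval()` upper
bound on starts below each query end, and a running maximum of ends to bound
the candidate window from the left. The result is identical to the all-pairs
brute force (this is a tested invariant, on a thousand random instances),
just near-linear instead of quadratic.

## Nearest-peak distances

`nearest_distances()` reports, for each query peak, the signed distance to
the closest reference peak on the same chromosome. Distances are between
interval *midpoints* (`floor((start + end) / 2)`), signed as reference minus
query. Midpoints are the natural anchor when both sets consist of short,
roughly symmetric enrichment intervals; edge-to-edge distances would
conflate width with proximity. Ties in absolute distance resolve toward the
reference with the smaller start, then the smaller index, which makes the
output deterministic. Query peaks on chromosomes with no reference peak are
omitted — not assigned an infinite distance — and counted in the
`n_omitted` attribute, so downstream summaries are never polluted by
sentinel values.

## The randomization null

The null model asks: *if the reference factor bound the genome at random,
how many overlaps (or how tight a distance distribution) would we see?*
`randomize_peaks()` re-places every peak uniformly on its own chromosome,
drawing each start from the integers $[0, L - w]$. Three properties are
exact, not approximate, and are asserted across 10,000 randomizations in the
test suite:

* the number of peaks on each chromosome is unchanged;
* the multiset of peak widths on each chromosome is unchanged;
* every randomized peak lies within its chromosome.

Randomized peaks may overlap one another: real peak sets are non-overlapping
post peak-calling, but imposing exclusion would change the null in a way the
procedure being modelled does not; a rejection-sampling
`no_self_overlap = TRUE` mode exists for sensitivity analysis. Peaks are
never moved across chromosomes, so chromosome-scale composition biases
(peak-rich versus peak-poor chromosomes) are held fixed by design.

`permutation_test()` randomizes the designated set (`shuffle = "reference"`
by default — either direction is legitimate and both are exposed because
overlap studies run the statistic both ways at different timepoints)
`n_perm` times and recomputes the overlap-count statistic each time. Two
summaries are reported:

* the **add-one empirical p-value** $(1 + \#\{T_i \ge T_{\mathrm{obs}}\}) /
  (n_{\mathrm{perm}} + 1)$, which counts ties, is never zero, and is the
  primary p-value (it is a valid p-value under exchangeability);
* the **strict exceedance count** $\#\{T_i > T_{\mathrm{obs}}\}$, because
  "the observed count was never exceeded" is how such results are usually
  stated; when it is zero the bound $p < 1/n_{\mathrm{perm}}$ is quoted.

The default `n_perm` is 10,000; 2,000 is the other commonly used setting
and reproduces the lighter published analysis this test mirrors — the two
figures circulate side by side and the package exposes both rather than
reconciling them. Each permutation seeds its own RNG substream derived from
(`seed`, iteration): a master `set.seed(seed)` draws one subseed per
iteration up front, so the null sequence is independent of evaluation order
and bit-identical across runs.

## Distance narrowness

`distance_narrowness()` quantifies the visual comparison "the true distance
distribution is much narrower than after randomization". It reports the
observed IQR of the signed distances, the IQR of each randomized
replicate, their ratio (observed over median null), and the
Kolmogorov–Smirnov statistic between observed and pooled null distances.
The KS statistic is computed on *absolute* distances: both signed
distributions are symmetric about zero, which caps the signed KS gap near
0.5 no matter how tight the observed distribution is, whereas on $|d|$ a
tight observed distribution against a broad null approaches the maximal
value 1. No significance cutoff is attached — narrowness is reported as a
descriptive pair (ratio $\ll 1$, KS near 1 for strong attraction; ratio
$\approx 1$ under independence, a tested calibration property). The default
of 200 randomizations differs from the overlap test's 10,000 deliberately:
the quantity consumed is the *median* null IQR, which stabilizes within a
couple of hundred replicates, and the per-replicate cost is a full
nearest-neighbour pass.

## Active and dormant origins

`classify_origins()` partitions the licensed-origin (Mcm) peak set: a peak
is an *active* origin when it overlaps at least one PCNA peak under the
criterion in force — reciprocal 25% by default, matching the definition
that requires the shared span to cover a quarter of both peaks — and
*dormant* otherwise. The partition is exact (active plus dormant equals the
input, duplicates included) and order-preserving.

`class_coverage()` then reports, for a third factor (gamma-tubulin, FoxM1,
...), the fraction of a class's origins that carry at least one peak of
that factor. The direction — fraction *of origins covered*, not fraction of
query peaks landing on origins — is the default because statements like
"gamma-tubulin was present in almost all identified active origins" are
statements about origins; the opposite direction is available via
`direction = "of_query"` since the criterion does not fix it.

### What recovery accuracy is achievable under planting noise

The synthetic origin scenario plants one width-matched PCNA peak per truly
active origin with a Normal$(0, \sigma)$ midpoint offset. With matched
widths $w$, the reciprocal 25% criterion holds iff the offset satisfies
$|d| \le 0.75\,w$, so the probability of recovering a truly active origin
is $2\Phi(0.75 w / \sigma) - 1$, and expected classification accuracy at
active fraction $f$ is

$$(1 - f) + f \, \mathbb{E}_w\!\left[2\Phi\!\left(\tfrac{0.75 w}{\sigma}\right) - 1\right].$$

At the generator defaults ($w$ lognormal with median 200 bp, $\sigma =
100$ bp, $f = 0.6$) this evaluates to about 0.90–0.92 — and it cannot
exceed $0.4 + 0.6\,(2\Phi(1.5) - 1) = 0.92$ even with degenerate widths.
The test suite checks the simulated accuracy against this closed form
(within 2.5 points) rather than against a round-number target; pushing
accuracy above 95% requires either $\sigma \lesssim 75$ bp or wider peaks.
This ceiling is a property of the planting noise model, not a defect of the
classifier, which is exact given its inputs.

## The synthetic generator

`sim_anchor_peaks()`, `sim_query_peaks()`, `sim_origin_scenario()` and
`sim_coverage_query()` generate the study conditions every statistical
claim in the package is validated on:

* **Genome**: 5 chromosomes of 50 Mb by default (`sim_genome()`) — large
  enough that chance overlap between thousand-peak sets is rare (expected
  background below ~2 of 1000 peaks), small enough for seconds-scale runs.
* **Widths**: lognormal, median ~200 bp (`sdlog = 0.35`), truncated to
  [50, 10000] bp by redrawing — emulating peak sets derived from chromatin
  fragmented to ~200 bp average size. A fixed width can be requested.
* **Placement**: chromosomes are chosen with probability proportional to
  length (uniform-per-chromosome would distort per-chromosome counts);
  starts are uniform given the chromosome.
* **Colocalization**: exactly `round(rho * n)` query peaks are planted at
  uniformly chosen anchors, midpoint offset Normal$(0, \sigma)$, the rest
  placed independently; the per-peak truth travels with the table as the
  `planted` column. Planted peaks are clamped (not wrapped) at chromosome
  ends; clamping events are counted and stay below 1% at defaults — a
  tested property.
* **Origins**: exactly `round(fraction_active * n)` origins, chosen at
  random, receive one width-matched PCNA peak each; optional background
  PCNA peaks are placed independently.

What the generator does **not** emulate: mappability and assembly gaps, GC
bias, the clustering of real peaks around genes and open chromatin,
correlated peak strengths, or inter-replicate variability in peak calling.
Passing tests therefore demonstrate the correctness and calibration of the
statistics under an idealized uniform-background genome; on real data the
within-chromosome randomization null is a *coarser* model of background
than, say, a mappability-masked shuffle, and p-values should be read
accordingly.

## The cohort cross-tabulation

`chi2_2x2()` is a thin, validated wrapper over the Pearson chi-squared test
(df = 1) for a 2×2 table of patient counts — here, low/high gamma-tubulin
staining against low/high PCNA staining — with the odds ratio
$(ad)/(bc)$ and per-group proportions (`group_proportions()`). The
continuity correction defaults to *off*: on the packaged ovarian-cohort
counts (`inst/extdata/ovarian_cohort_counts.csv`, the table is
[[38, 19], [79, 11]]) the uncorrected statistic is 9.575 with
$p \approx 2.0 \times 10^{-3}$, the Yates-corrected one gives
$p \approx 3.9 \times 10^{-3}$, and the p-value originally reported
alongside this cohort ($2.2 \times 10^{-3}$) is closer to the uncorrected
recomputation. None of the choices reproduces that figure exactly — the
cohort totals (57 + 90 = 147 of 154 patients) suggest the tested table may
have differed slightly — so the package reports its own computation and
documents the discrepancy rather than asserting the printed value. The
analytic p-value is cross-checked in the test suite against an independent
Monte-Carlo label permutation (hypergeometric sampling of the table with
margins fixed, 100,000 draws).

## Numerical and design choices, in one place

* Coordinates 0-based half-open throughout (BED convention); conversion to
  the 1-based convention of GRanges happens only at I/O boundaries in
  tests.
* Overlap threshold comparisons are inclusive (`>=`).
* Midpoints use `floor((start + end)/2)`; signed distance is reference
  minus query; distance ties break toward the smaller reference start.
* Empirical p-values use the add-one estimator with ties counted; the
  strict exceedance count is reported for parity with "never exceeded"
  phrasing.
* Uniform starts are drawn as `floor(runif() * (L - w + 1))` with a
  defensive clamp at `L - w`.
* Unknown chromosomes in BED input error by default; `"drop"` is opt-in
  and warns with a count.
* An empty query set yields a degenerate test: observed 0, all null
  statistics 0, $p = 1$.
* An empty origin class yields coverage 0 with an `empty_class` flag, not
  an error.

## Problem sizes used in the validation suites

The test suite validates the statistical claims at these scales, chosen so
the whole suite runs in about two minutes on one CPU while keeping Monte
Carlo noise well inside the asserted tolerances:

* headline colocalization run: 5 × 50 Mb genome, 1000 + 1000 peaks,
  $\rho = 0.8$, 2000 randomizations (zero strict exceedances, $p < 0.005$);
* type-I calibration: 500 independent-placement datasets on 1 × 10 Mb with
  800 + 800 peaks, 199 randomizations each — the denser genome raises the
  expected background overlap count to ~15–20 so the integer statistic's
  discreteness does not dominate the rejection-rate comparison, which is
  made against the exact binomial 99% interval around 0.05;
* sweep-versus-brute-force: 1000 random instances with up to 50 × 50
  peaks, all modes, thresholds uniform in (0.01, 1];
* randomization contract: 10,000 randomizations of a 120-peak,
  3-chromosome set;
* origin recovery: 1000 origins, active fraction 0.6, offset SD 100 bp
  (accuracy checked against the closed form above), coverage planting at
  97%/50% with offset SD 25 bp so the planted peaks clear the overlap
  criterion essentially surely and the check isolates the bookkeeping;
* cohort: 100,000 Monte-Carlo label permutations.

## Limitations

* The randomization null conditions on per-chromosome peak counts and
  widths but assumes uniform placement within chromosomes; regions that are
  unmappable or unassembled are treated as available.
* Nearest-distance analysis uses midpoints only; for very wide, asymmetric
  domains an edge-based distance may be preferable.
* The origin classifier is a deterministic rule on one pair of peak sets;
  it does not model peak-calling uncertainty, replication timing, or origin
  efficiency.
* The chi-squared stage covers a single 2×2 table; stratified or matched
  cohort designs are out of scope.
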