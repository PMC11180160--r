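---
title: "Methods: segregation genetics and deletion discovery at the INO locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation genetics and deletion discovery at the INO locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inodel)
```

## Scientific model

`inodel` analyses a monogenic recessive seedless trait in sugar apple
(*Annona squamosa*) whose causal lesion is a large clean deletion spanning
the *INNER NO OUTER* (*INO*) locus. The package treats the problem as four
connected questions:

1. **Is the trait monogenic recessive?** Progeny counts from controlled
   crosses are tested against Mendelian ratios (3:1 in F2, 1:1 in a
   backcross to the seedless parent, 1:2:1 for a codominant marker) with
   Pearson chi-square goodness-of-fit tests, and independent families are
   combined with a pooled/heterogeneity partition.
2. **How tightly is the marker linked to the trait?** With zero observed
   recombinants among informative chromosomes, linkage cannot be proven at a
   point; instead a chi-square bound gives the smallest map distance that the
   data reject.
3. **What is the lesion?** Short-read alignments against a wild-type
   reference are scanned for coverage gaps; soft-clipped reads at the gap
   flanks are assembled into a junction contig, and the breakpoint is
   characterised base-exactly and written as a VCF `<DEL>` record.
4. **Does the lesion cosegregate and type cleanly?** An in-silico PCR model
   predicts the codominant band assay, and SSR band matrices are summarised
   with Jaccard distances.

A seed-free synthetic-data layer generates crosses with a linked marker,
deletion-carrying genome pairs, projected read alignments and band matrices,
so every pipeline stage can be validated against known truth.

## Statistical methods and parameter choices

### Goodness of fit

`chi_square_gof()` computes the uncorrected Pearson statistic with
`df = classes − 1` (delegating to `stats::chisq.test(correct = FALSE)`).
No continuity correction is applied because the historical plant-genetics
literature this reproduces uses the plain statistic; the package documents
rather than hides the chi-square approximation error (the test suite
measures the worst-case deviation from the exact binomial tail at very
small totals). The default `alpha = 0.05` is the conventional screening
level; `p == alpha` counts as non-significant. Zero *observed* cells are
allowed (they occur in real tables); zero *expected* cells (a zero ratio
term) are rejected as invalid input.

### Heterogeneity partition

`heterogeneity_partition()` uses the classical identity

> total (sum of per-family chi-squares) = pooled (chi-square on summed
> counts) + heterogeneity,

with heterogeneity `df = (families − 1)(classes − 1)`. The identity is
asserted in the tests to `1e-9`; a small heterogeneity statistic supports
pooling families as draws from one segregating population.

```{r}
f2 <- list(cross_family("M1", "F2", c(99, 43)),
           cross_family("M2", "F2", c(190, 71)),
           cross_family("M3", "F2", c(69, 33)))
heterogeneity_partition(f2, ratio_hypothesis(c(3, 1)))
```

### Linkage bound from zero recombinants

`count_informative_chromosomes()` credits each progeny plant by how many
informative marker-bearing chromosomes it contributes: an F2 heterozygote
contributes 1 (only the deletion-bearing chromosome is informative), an F2
homozygous deletion plant 2, a backcross (to the seedless parent) plant 1,
and all other classes 0. A recombinant is a genotype–phenotype mismatch.
`distance_rejection_test()` then asks: if the true distance were `d` cM,
would the observed number of recombinants be surprising? The default
`recombinant_class_term` variant uses only the recombinant class,
`(O − E)² / E` with `E = n·d/100`, which equals `E` exactly when `O = 0`.
`min_rejectable_distance()` inverts the test: with zero recombinants the
closed form is `100 · qchisq(1 − alpha, 1) / n`; with observed recombinants
it falls back to bisection. Distances are restricted to `(0, 50)` cM, the
meaningful range for a single-interval recombination fraction.

```{r}
ct <- list(n_chromosomes = 114, n_recombinants_observed = 0)
distance_rejection_test(ct, 3.5)
min_rejectable_distance(ct)
```

## Deletion discovery

All genomic coordinates are **0-based, half-open** internally; 1-based
coordinates appear only at the VCF boundary.

* `depth_profile()` computes per-base aligned depth via cumulative sums of
  interval start/end deltas — O(reads + reference length), no per-base loop.
* `detect_gaps()` finds runs of depth ≤ `max_internal_depth` (default 2,
  tolerating stray mismapped reads), discards runs shorter than
  `min_gap_len` (default 100, well below any deletion of interest but above
  alignment noise), and merges low-coverage runs separated by coverage
  spikes **strictly shorter** than `max_spike_len` (default 500). The strict
  inequality is deliberate: a spike exactly at the threshold keeps the runs
  split, so `max_spike_len = 1` means "merge nothing". Merging repeats until
  a fixed point.
* `collect_junction_reads()` keeps reads whose soft-clip (≥ `min_clip`,
  default 10 bases — short clips are untrustworthy) abuts a gap edge within
  `window` (default 5) bases.
* `assemble_junction()` is a greedy overlap-layout-consensus assembler with
  exact suffix–prefix overlaps of ≥ `min_overlap` (default 20) bases and
  deterministic lexicographic tie-breaking, sufficient for error-free or
  error-corrected clipped reads at a single junction. It is **not** a
  general-purpose assembler.
* `call_deletion()` places the junction contig by anchoring a unique
  maximal-extension seed on each side of the junction (`min_anchor`
  default 20; ambiguous anchors raise an error rather than guessing),
  then **left-aligns** the implied deletion and reports microhomology as the
  number of bases the breakpoint can slide right. Every equivalent placement
  therefore maps to one canonical call, which is what the recovery tests
  compare against.
* `diff_alleles()` applies the same anchoring to two whole allele sequences,
  and `insilico_pcr()` predicts amplicons (plus-strand forward primer,
  reverse-complemented reverse primer, inclusive primer footprints, products
  above `max_amplicon = 3000` suppressed — a practical endpoint-PCR limit).

```{r}
pair <- simulate_genome_pair(60000, c(20000, 28000), seed = 1)
aln <- simulate_alignments(pair, depth = 20, seed = 2)
detect_deletion(aln, pair$reference)$call
```

## Synthetic data: what it does and does not emulate

`simulate_cross()` draws gametes from a two-locus coupling-phase model in
which marker and trait alleles recombine with probability `d/100`; at
`d = 0` the marker is inside the deletion and cosegregates perfectly. The
default `distance_cM = 0` encodes the study condition of a marker physically
internal to the lesion — it is a modelling statement, not a tuning dial.

`simulate_genome_pair()` builds an i.i.d. random reference (default GC
fraction 0.5) and its deletion allele; `simulate_alignments()` projects
error-free or uniformly erroneous reads (default `read_len = 150`,
`depth = 20`) onto the reference by truth, soft-clipping junction-spanning
reads on the shorter side. The generator emulates clean homozygous
deletions under even coverage. It does **not** emulate: heterozygous
samples (mixed coverage at the gap), GC-coverage bias, indel sequencing
errors, repetitive genomes beyond chance repeats, or mapping ambiguity —
alignment is by construction, not by a mapper. Conclusions about real data
therefore rest on the analysis components, not on the generator's realism.

Problem sizes in the tests (references of 50–200 kb, deletions of 0.5–20 kb,
15–20× depth) are the package's own choice: large enough that a deletion
junction is flanked by ample unique anchor sequence and a coverage gap is
unambiguous, small enough that a 100-replicate property test runs in
minutes on one CPU.

## Numerical and design decisions

* Chi-square p-values come from `pchisq(..., lower.tail = FALSE)` via
  `stats::chisq.test`; published-value comparisons in the tests are made at
  the printed precision (absolute, 2–3 decimals), while cross-checks against
  the independent hand formula are at `1e-12`.
* The partition identity and all closed forms are asserted to tight absolute
  tolerances; Monte Carlo assertions use multi-sigma binomial bounds so a
  single unlucky seed cannot fail the suite.
* Jaccard distances delegate to `vegan::vegdist(method = "jaccard",
  binary = TRUE)`; pairs with no bands at all are reported as `NA` with an
  `undefined_pairs` attribute rather than imputed.
* FASTA and SAM/BAM I/O delegate to `Biostrings` and
  `Rsamtools`/`GenomicAlignments`; minimal SAM and VCF 4.2 writers are
  implemented by hand because only a small, fixed subset of each format is
  produced.

## Limitations

* The linkage bound is a rejection bound, not a confidence interval for the
  map distance; with zero recombinants no point estimate exists.
* The deletion caller targets single clean deletions (optionally with a
  short insertion or tandem-duplication signature at the junction); it does
  not call other SV classes, nested events, or heterozygous genotypes.
* The junction assembler requires exact overlaps; reads with sequencing
  errors inside the clip must be corrected upstream.
* In-silico PCR assumes perfect primer specificity at `max_mismatch = 0`
  and does not model primer thermodynamics.
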