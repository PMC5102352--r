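---
title: "Mapping a dominant locus by bulked-segregant resequencing and backcross fine mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant locus by bulked-segregant resequencing and backcross fine mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

# The mapping problem

A single locus with a dominant donor allele (brown seed coat) segregates 1:1
in a backcross population: four rounds of backcrossing a brown-seeded donor
line into a yellow-seeded recurrent parent, keeping a locus carrier each
round, give a BC4 near-isogenic population. `bsamap` localises the locus two
ways and intersects the answers:

* a **bulked-segregant scan** of pooled whole-genome resequencing of the two
  phenotype classes, and
* **fine mapping** by recombinant counts between markers and the phenotype in
  the full population.

Both routes are driven by `run_bsa()` and `run_finemap()`; every stage is
also exposed as a function so it can be used or replaced in isolation.

# The bulked-segregant model

## SNP index and ΔSNP index

At sites where the two inbred parents are homozygous for different alleles,
a pool's *SNP index* is the fraction of its reads carrying the allele of the
non-reference parent (the brown donor parent is the reference, so the index
measures the yellow-parent allele). `select_parent_homozygous()`
operationalises "homozygous parent" as *all* of a parent's reads supporting
one allele with depth at least `min_parent_depth` (default 4 reads) — read
data carry no stronger purity signal at these depths, and the threshold is a
flag, not a constant. Swapping the reference parent maps every index $i$ to
$1 - i$ and the delta to its negative; a property test pins this involution.

In a BC4 bulk the expected index is the same in both pools at unlinked sites,
while at the causal locus the brown bulk (all heterozygous) has index 1/2 and
the yellow bulk (all recurrent-homozygous) index 1. The *ΔSNP index* is
defined **brown-bulk minus yellow-bulk** — the subtraction order is a
convention, exposed by the pool order given to `snp_index_table()`; under it
a dominant brown locus shows Δ ≈ −1/2.

## Site filters

Two removal rules act on the per-site table (`apply_filters()`):

* sites whose index is below 0.3 *and* depth below 7 reads *in both pools* —
  the strictest reading of the joint low-index/low-depth pattern, which flags
  scattered mis-mapped reads rather than true segregating sites;
* sites with a missing index (zero depth) in either pool.

The removal tally is reported per rule and always sums to input minus output.

## Sliding-window scan

`sliding_window_profile()` averages each pool's indices in windows of 1 Mb
advanced by 1 kb (both configurable), anchored at position 1, with 1-based
inclusive spans; trailing truncated windows are emitted and flagged
`partial`. The window statistic is the unweighted mean of member SNP indices
(a depth-weighted mean is available behind `weighted = TRUE`). Windows with
fewer than `min_snps_per_window` SNPs (default 10) are flagged ineligible and
never called significant — a guard against single-SNP spikes. The
implementation is a cumulative-sum scan; its exact agreement with a naive
per-window mean is part of the test suite.

## Null confidence band

`null_delta_quantiles()` simulates the null ΔSNP index for a given bulk size
and read depth: each replicate draws every bulk plant's genotype
(heterozygous with probability ½, the backcross null; the probability is a
parameter `het_prob`), forms the true pool allele frequency, then draws the
given number of reads binomially per pool. The two-stage draw keeps the
bulk-size variance component that a one-shot binomial on the expected
frequency would lose. Quantiles at $(1 \pm \text{confidence})/2$ are
tabulated on a depth grid (default 1–100, 10,000 replicates) and looked up by
nearest grid depth for each window's mean per-pool SNP depth.

**Discreteness at low depth.** At depth $d$ the per-site delta is supported
on multiples of $1/d$; at the study depth (15×) the null mass at $\pm 1/3$ is
about 2.5% per side. Exactly nominal coverage is therefore unattainable: the
attainable two-sided coverages nearest 95% are ≈ 91.4% (band endpoints
excluded) and ≈ 96.4% (included). The package takes the conservative
convention — band endpoints are the empirical quantiles and a window is
significant only *strictly outside* the band — so attained coverage is at or
above the nominal level. Window-mean deltas, being averages over many SNPs,
are far less granular, and the conservatism mainly affects per-site use. A
corollary: at depth 1 even Δ = 1 is a null-typical value (probability ≈ 0.19)
and can never be significant; the band only separates signal from noise once
depth makes extreme deltas rare.

`extract_candidate_intervals()` reports maximal runs of significant windows;
runs separated by at most `merge_gap_bp` (default 0 — raw runs) are merged,
and overlapping windows coalesce naturally. Intervals carry their peak delta
and window count, and are written as BED (0-based half-open on disk,
converted from the internal 1-based inclusive convention; the conversion is
round-trip tested).

# Fine mapping

`count_recombinants()` scores a plant recombinant when its marker genotype
contradicts its phenotype under dominant-donor coding — heterozygous yet
yellow, or recurrent-homozygous yet brown (`donor_dominant = FALSE` flips the
coding). Missing calls drop out of $n$. The map distance is the Kosambi
function $d = 25\,\ln\frac{1+2r}{1-2r}$ cM with closed-form inverse
$r = \tanh(d/50)/2$; distances are reported to three decimals, the
customary precision of SSR maps. `segregation_test()` is the 1-df chi-square
$\,(a-b)^2/(a+b)$ for the expected 1:1 ratio.

`flanking_interval()` locates the cosegregating block ($k = 0$) and takes the
nearest marker with $k > 0$ on each side. Two boundary conventions are
implemented: `"outer"` (default) spans from the left flank's lowest
coordinate to the right flank's highest — i.e. the flanking marker spans are
included, the convention that reproduces the published style of final bound —
while `"inner"` uses each flanking span's edge facing the block. A side with
no flanking marker yields an open-ended interval, flagged and warned.

# Combining the two routes

`interval_intersect()` is plain interval algebra on 1-based inclusive
coordinates, `[max(starts), min(ends)]`. Interval sizes are reported as
**end − start** (not the inclusive base count `end − start + 1`): sizes in
this literature are differences of printed bound coordinates, and the
convention matters at the reporting granularity (kb rounded to integers, Mb
to one decimal — `length_kb()`, `total_span_mb()`). `count_genes()` counts
annotation features overlapping the final region by at least one base
(inclusive on both sides); containment-only counting would need the end-user
to say so explicitly, and overlap is the weaker, safer claim.

# The synthetic-data generator

The simulator exists so that the pipeline's statistical behaviour can be
tested end to end; its defaults are the study conditions: BC4, 1,739 plants,
bulks of 20 + 20, mean pool depth 15×, read-miscall rate 0.001.

* **Meiosis**: crossover count per gamete is Poisson with the chromosome's
  genetic length (Morgans) as mean, positions uniform, no interference.
  This is the simplest model consistent with the small-distance regime in
  which the Kosambi function is actually exercised here (at 1 cM, Haldane,
  Kosambi and the identity map agree to ~1%); the gamete generator is a
  single internal function and is swappable.
* **Genetic ↔ physical map**: uniform cM/bp per chromosome. No recombination
  map is assumed; the default chromosome (37 Mb, 1.2 Morgans ≈ 3.2 cM/Mb) is
  a realistic *B. rapa* scale.
* **Selection**: each backcross generation keeps one progeny heterozygous at
  the selection locus as the next carrier; nothing else is selected. A
  consequence worth knowing: the donor segment around the locus erodes
  stochastically, so a marker at map distance $r$ from the locus is still
  heterozygous in the BC$n$ carrier only with probability $(1-r)^{n-1}$.
  In the small fraction of pedigrees where a nearby marker's donor allele is
  lost before the final generation, every carrier plant scores as a
  "recombinant" at that marker — real screens detect this as a monomorphic
  marker and drop it. Tests of the $k \approx n \cdot r$ expectation
  therefore use a single meiosis (BC1) where the relation is exact.
* **Phenotype**: donor allele dominant (carrier = brown), fixed by the
  observed 1:1 backcross segregation with a yellow recurrent parent.
* **Bulks and sequencing**: uniform sampling without replacement within
  phenotype; per-site depth Poisson; each read misreports its allele with a
  symmetric probability (no mapping bias, no indels, no multi-allelic sites,
  no read-level artifacts — FASTQ-level simulation is out of scope).

Invariants covered by tests: donor-allele frequency exactly 0 / 0.5 in the
yellow / brown bulk at the locus; heterozygosity $2^{-n}$ at unlinked loci
after $n$ backcrosses; bit-for-bit reproducibility given the seed.

What passing tests on this generator do **not** show: robustness to mapping
bias, depth heterogeneity along the genome, residual heterozygosity in the
parents, or misphenotyping — all of which real data contain and the
generator deliberately omits.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run the scan at desk scale —
one chromosome, 2,000 parent-differential SNPs (the study had ~780k
genome-wide; SNP density beyond a few per window only sharpens the window
means), 10,000 null replicates, 50 seeded recovery runs — chosen so the whole
suite completes in a few minutes while leaving Monte-Carlo error well inside
the asserted tolerances. One master seed drives every stage through fixed
offsets (`run_config()`), so each stage can be re-run in isolation and every
artifact (window TSV, threshold TSV, candidate BED, JSON summary) regenerates
byte-identically from config + seed.

# Known limitations

* The null band assumes a fixed representative depth per window
  (nearest-grid lookup of the mean per-pool SNP depth); no per-SNP depth
  mixture is simulated.
* No multiple-testing control across windows (the confidence band is
  per-window, as in the windowed-scan tradition); no tricube smoothing or
  G-statistic alternatives.
* Fine mapping assumes a single-locus, fully penetrant dominant trait and
  error-free marker genotyping.
* Multi-point map ordering is out of scope: markers are ordered by physical
  position, and cosegregating markers tie at 0 cM.
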