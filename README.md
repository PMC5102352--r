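# bsamap

Localising a single dominant locus in a backcross population by two
complementary routes, and intersecting them.

The motivating problem is classic plant-gene mapping: a seed-coat-colour gene
in *Brassica rapa* segregates 1:1 in a BC4 population built by four selective
backcrosses of a brown-seeded donor into a yellow-seeded recurrent parent.
Two independent localisations are then combined:

1. **Bulked-segregant resequencing (BSA-seq / QTL-seq).** DNA of 20 plants of
   each phenotype is pooled and sequenced to ~15×. At every SNP that is
   homozygous-different between the parents, each pool's **SNP index** is the
   fraction of its reads carrying the allele of the non-reference parent
   (the brown parent serves as reference). Genome-wide, both pools sit near
   the expected backcross frequency; at a trait-linked locus they diverge.
   The **ΔSNP index** (brown-bulk index minus yellow-bulk index) is averaged
   in 1-Mb windows advanced in 1-kb steps, and windows are called significant
   against a **simulation-based null band**: the null distribution of Δ at a
   given read depth is obtained by resampling bulks of 20 genotypes
   (heterozygous with probability ½) and then binomial read draws, and its
   2.5%/97.5% quantiles form the 95% confidence band. Runs of significant
   windows become candidate intervals.
2. **Fine mapping.** In the full population (1,739 plants) each marker's
   recombinants with the phenotype are counted (`H` + yellow or `A` + brown
   under a dominant donor allele), the recombination fraction r = k/n is
   converted to a map distance with the **Kosambi function**
   d = 25·ln((1+2r)/(1−2r)) cM, and the physical interval between the closest
   flanking markers of the cosegregating block is extracted.

The final candidate region is the intersection of the two intervals; genes
overlapping it are counted from a GFF3/BED annotation. A synthetic-data
module (`simulate_cross()`, `make_bulks()`, `simulate_pool_depths()`,
`simulate_marker_screen()`) emulates the breeding scheme, pooled sequencing
(Poisson depth, symmetric read-miscall errors) and marker genotyping, so the
entire pipeline runs with no external data.

## Worked example

Simulate the study design on one 37-Mb chromosome (1.2 Morgans, 2,000
parent-differential SNPs, BC4 of 1,739 plants, 20+20 bulks, 15× pools) and
scan it:

```r
library(bsamap)

genome <- simulate_genome("A09", 37e6, n_snps = 2000, morgans = 1.2, seed = 20)
locus  <- genome$snp_positions$A09[which.min(abs(genome$snp_positions$A09 - 18.5e6))]
cfg <- run_config(seed = 42, genome = genome,
                  design = cross_design(selection_pos = locus))
res <- run_bsa(cfg)
res$candidates
#>   chrom    start      end peak_delta n_windows
#> 1   A09 10703001 24426000 -0.5297258     12586
#> 2   A09 24980001 26890000 -0.3561357       619
```

The top interval contains the simulated locus (18,503,764 bp) with a peak
ΔSNP index near −0.5 — the value expected at a dominant locus, where the
brown bulk is uniformly heterozygous (index ½ for the yellow-parent allele)
and the yellow bulk fixed (index 1). The sign is negative because Δ is
brown minus yellow. Intervals are broad at this stage: the whole chromosome
is linked to the locus, which is exactly why the marker route is run too.

Fine mapping with a 7-marker screen in which the flanking markers show 10
and 2 recombinants among 1,739 plants:

```r
res_fm <- run_finemap(screen,
  candidates = data.frame(chrom = "A09", start = 17830000, end = 18934000))
res_fm$map[c("marker", "k", "n", "cM")]
#>      marker  k    n     cM
#> 1     BrA10 10 1739 0.5751
#> 2     BrA11  0 1739 0.0000
#> ...
#> 7 BrID10685  2 1739 0.1150
res_fm$interval            # flanking-marker physical interval
#>   chrom    start      end        label
#> 1   A09 18255838 19342792 fine_mapping
res_fm$final_regions       # intersected with the scan candidate
#>   chrom    start      end        label length_kb
#> 1   A09 18255838 18934000 final_region       678
```

The two flanking markers map 0.575 and 0.115 cM from the locus, and the
intersection of the 18,255,838–19,342,792 fine-mapping interval with a
17.83–18.93 Mb scan interval is a 678-kb final region (interval sizes are
reported as `end − start`).

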