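Package: bsamap
Title: Bulked-Segregant Resequencing and Fine Mapping of a Seed-Coat-Colour Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localises a single dominant locus segregating in a backcross
    population by two complementary routes and intersects them. The bulked-segregant
    route computes per-SNP indices from pooled allele depths of two phenotype bulks,
    filters low-confidence sites, scans chromosomes with a sliding-window delta
    SNP index, and calls candidate intervals against simulation-based null
    confidence bands. The fine-mapping route counts recombinants between markers
    and the locus in a large backcross population, converts recombination
    fractions to Kosambi map distances, and derives the physical interval between
    the closest flanking markers. A synthetic-data module simulates the breeding
    scheme (selective backcrosses, phenotype bulks, pooled short-read allele
    depths, marker screens) so the whole pipeline runs and is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    vcfR,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
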