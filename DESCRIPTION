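Package: inodel
Title: Segregation Genetics and Deletion Discovery for the Seedless
    Sugar-Apple Trait at the INO Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the genetic and genomic analysis of a monogenic
    recessive seedless (stenospermocarpic) trait in Annona squamosa caused
    by a large deletion spanning the INNER NO OUTER (INO) locus. Provides
    Mendelian segregation goodness-of-fit tests with pooled and
    heterogeneity chi-square partitions across cross families, a
    cosegregation-based chi-square bound on marker-trait map distance,
    clean-deletion discovery from soft-clipped short-read alignments
    (coverage-gap detection, junction contig assembly, breakpoint
    characterisation and VCF output), in-silico PCR and codominant
    band-pattern genotyping, Jaccard-based SSR band-matrix diversity, and
    a synthetic-data generator that simulates crosses with a linked
    marker, deletion-carrying genomes, projected read alignments and band
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    stats,
    tools,
    utils,
    vegan
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
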