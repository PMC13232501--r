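Package: crossoverBSA
Title: Haplotype Painting, Crossover-Rate Estimation, and Bulk Segregant
    Association on Recombinant X Chromosomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of bulk segregant designs in which two near-isogenic
    parental lines are allowed to intermate freely for many generations and
    recombinant males are sequenced individually. Provides haplotype painting
    of hemizygous X chromosomes from informative SNPs, region-wise crossover
    counting with per-Mb per-meiosis rate estimates, bootstrap confidence
    intervals and an exact conditional Poisson rate test, pool-based Fisher
    association with Bonferroni correction, per-region parental-fraction
    comparisons, and a forward meiosis simulator that reproduces the
    statistical structure of such a design, including crossover-placement
    suppression inside SNP-dense blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    GenomeInfoDb,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Genetics, SNP, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
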