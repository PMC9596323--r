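Package: mhcdiv
Title: Genome-Wide and MHC Diversity, Supertyping, and Kinship-Aware
    Association Models for Amplicon-Genotyped Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare genome-wide genetic diversity and kinship with
    diversity and complementarity at the major histocompatibility complex
    (MHC) in small pedigreed cohorts. Covers MHC allele calling from amplicon
    read pools (locus assignment, rare k-mer artifact filtering, read-fraction
    thresholds with cross-individual rescue, known/new classification),
    functional supertype definition (translation, positively selected site
    screening, z-descriptor matrices, average-linkage clustering with a
    minimum-size branch cut), genome-wide summaries from biallelic SNP
    matrices (LD pruning, heterozygosity, standardized multilocus
    heterozygosity, KING-robust pairwise kinship), per-individual MHC
    heterozygosity and dyadic complementarity indices, and a statistical
    layer with kinship-random-effect linear mixed models, bounded-influence
    robust Poisson regression with Wald-type nested tests, multiple-testing
    correction, collinearity diagnostics, and a minimum-detectable-effect
    power solver. A seeded synthetic-data generator (pedigrees, SNP
    genotypes, MHC haplotypes, amplicon reads with sequencing error and PCR
    chimeras, dyadic counts) makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
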