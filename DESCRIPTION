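Package: cmiscan
Title: Conditional Mutual Information Scans for Breed-Discriminative SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide identification of SNPs whose two-locus genotypes
    discriminate two populations, using a conditional mutual information
    ("mutual information extractor") score on adjacent SNP pairs with a
    label-permutation significance test.  Includes companion analyses:
    per-chromosome genotype-class distributions, heterozygosity-pattern
    tables, per-gene genotype profiles, a mitochondrial summary,
    hypergeometric gene-set over-representation, a from-scratch
    cross-population extended haplotype homozygosity (XP-EHH) statistic
    for method comparison, and a truth-tagged two-population genotype
    simulator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
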