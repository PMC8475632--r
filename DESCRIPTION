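Package: psassoc
Title: Population-Structure Association Testing for Inbred-Strain GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Haplotype-based genetic mapping and population-structure (PS)
    assessment for panels of fully homozygous inbred mouse strains. Builds
    maximal haplotype blocks (>= 4 SNPs, 2-5 haplotypes) from strain
    genotypes, scores block-phenotype association by one-way ANOVA with
    eta-squared effect sizes and noncentral-F power, and applies an inverted
    PS association test: a MANOVA of genetic-relationship-matrix (or
    identity-by-state) principal-component coordinates on the block's
    haplotype grouping, with Benjamini-Hochberg adjustment and PS+/PS-
    classification. Includes Tracy-Widom assessment of leading eigenvalues,
    IBS hierarchical sub-population clustering, LD pruning, and a
    Balding-Nichols style simulator of structured inbred panels with planted
    causative blocks and replicate-level phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    GenomicRanges,
    IRanges,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
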