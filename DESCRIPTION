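Package: xciescape
Title: Allele-Specific Calling of X-Inactivation Escape Genes in Skewed F1 Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for haplotype-resolved analysis of X-chromosome inactivation
    (XCI) in an F1 hybrid mouse system with completely skewed XCI. Provides SNP
    catalog handling and pseudo-genome substitution, segregation of high-quality
    uniquely mapped reads into parental-allele categories, diploid RPKM and
    haploid Xi-/Xa-SRPM expression metrics with an experiment-level mapping-bias
    ratio, a binomial model of the Xi-expression proportion with bias-corrected
    Wald confidence limits and three-criterion escape-gene classification,
    exact-binomial classification of allele-specific ChIP-seq peaks against a
    chromosome-level background, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
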