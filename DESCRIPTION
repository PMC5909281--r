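Package: pooldecon
Title: Donor Proportion Estimation in Pooled DNA Samples by
    Expectation-Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the proportion of each known donor in a pooled DNA
    sample from whole-genome sequencing read counts at bi-allelic autosomal
    SNPs, using an expectation-maximization algorithm over a panel of known
    donor genotypes.  Works at very low coverage (1X) when enough SNPs are
    observed, so pooled samples can be deconvolved without exogenous
    barcodes.  Includes a simulation framework (uniform minor-allele
    frequencies, Hardy-Weinberg genotypes, uniform copy numbers, binomial
    read sampling) for parameter-recovery benchmarking across donor count,
    SNP count and read depth, readers for donor genotype panels (VCF) and
    pooled allele tallies (samtools mpileup text or TSV), and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
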