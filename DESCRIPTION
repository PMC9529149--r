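Package: privsnp
Title: Species-Diagnostic Private SNP Panel Selection and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reduces a genome-wide biallelic SNP set to a small panel of
    species-informative "private" SNPs (loci segregating in exactly one
    population and fixed in all others) by resampling stability selection,
    with per-locus Weir & Cockerham (1984) Fst filtering, and validates the
    panel's discriminatory power by principal component analysis,
    K-means/BIC cluster-number inference, and discriminant analysis of
    principal components (DAPC) with posterior membership probabilities.
    Includes per-population allele-frequency and heterozygosity statistics,
    call-rate/MAF quality control, VCF and tabular genotype input, and a
    Balding-Nichols-based synthetic genotype simulator with planted private
    loci for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
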