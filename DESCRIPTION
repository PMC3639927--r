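Package: lcepop
Title: Population Genetics of the LCE3C_LCE3B 32-kb Deletion from Pooled
    aCGH and Individual Genotypes
Version: 0.1.0
Authors@R:
    person("lcepop", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for surveying a common biallelic
    copy-number deletion (the 32-kb LCE3C_LCE3B deletion on chr1q21)
    across human populations.  Implements rule-based detection of
    copy-number variable regions from dye-swap pooled array-CGH
    log2-ratio profiles with a second windowed caller and a two-caller
    consensus filter; per-population genotype and allele frequency
    estimation with one-degree-of-freedom Hardy-Weinberg chi-square
    tests; EM estimation of two-locus CNV-by-SNP haplotype frequencies
    with D, D' and r-squared linkage disequilibrium; Spearman rank
    correlation of pooled hybridisation intensity against deletion
    allele frequency; and a seeded synthetic-data generator emulating
    HGDP/HapMap-style population samples and pooled hybridisations so
    the whole pipeline is testable without access to the original
    arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
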