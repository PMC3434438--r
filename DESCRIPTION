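Package: dmafscan
Title: Difference in Minor Allele Frequency Tests with Sliding-Window
    Localization of Region-Based Association Signals
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Region-based case-control association testing for rare and
    common sequence variants using the difference in minor allele
    frequency (DMAF) statistic with permutation p-values; a sliding-window
    scan with Westfall-Young step-down permutation correction for the
    multiple windows of a given size, including localization of the causal
    sub-region; a coalescent-based simulation framework (haplotype pools,
    multiplicative disease models with risk and protective variants,
    prevalence calibration) for power, type I error and localization
    studies; and readers/writers for VCF genotypes, ms-format haplotypes
    and phenotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
SystemRequirements: Python 3 with msprime (optional; only needed to run
    the built-in coalescent engine, ms-format input works without it)
Config/testthat/edition: 3
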