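Package: adopanel
Title: Allelic-Dropout Risk Screening and Detection for PCR Amplicon Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audit tools for allelic dropout (ADO) in PCR-based targeted
    sequencing panels. Screens primer binding sites for population variants
    that threaten allele-specific amplification, tiers findings by distance
    from the primer 3' terminus and by carrier frequency, detects dropout
    signatures in per-amplicon allele observations (underrepresented markers,
    pseudo-homozygosity, overlapping-amplicon and cross-platform
    discordance, trio conflicts), attributes candidate causes, and
    summarises panel-wide risk under Hardy-Weinberg carrier probabilities.
    Includes a phased-haplotype simulator with an allele-specific
    amplification-efficiency dropout model and a calibrated negative-binomial
    read-depth model for building reproducible synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
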