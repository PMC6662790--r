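Package: founderscan
Title: Carrier Haplotype Discovery and IBD Sharing in Founder Populations
Version: 0.1.0
Authors@R: person("founderscan", "maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering cryptic carriers of ultra-rare actionable
    variants in population isolates from SNP-array haplotypes. Implements
    consensus carrier-haplotype definition over incremental physical windows
    around an array-absent focal variant, cohort-wide haplotype scanning,
    variant-resolution measurement of shared haplotype length, a transparent
    opposite-homozygote identity-by-descent segment caller with sharing
    summaries and cousin-degree calibration, standard array genotype QC
    (call rate, exact Hardy-Weinberg test, Mendelian-error masking, ancestry
    principal-component outliers), QTc phenotype statistics with Bazett
    correction, and a gene-dropping simulator of isolate cohorts with
    recorded and unrecorded kindred relationships that provides ground truth
    for every step.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
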