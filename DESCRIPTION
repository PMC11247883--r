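Package: corsivr
Title: Screening for Correlated Regions of Systemic Interindividual
    Methylation Variation in Multi-Tissue WGBS Data
Version: 0.1.0
Authors@R:
    person("corsivr", "maintainers", email = "corsivr@example.org",
           role = c("aut", "cre"))
Description: A two-step screen for correlated regions of systemic
    interindividual variation (CoRSIVs) in whole-genome bisulfite
    sequencing data: 100-bp binning with CpG coverage-adequacy rules,
    CpG-SNP masking against genotype data, individual-level methylation
    residuals, block building, the systemic interindividual variation
    index (SIVI), a library-scrambling permutation null, matched
    control-region sampling, genomic-context annotation (TSS/TES, gene
    body, variants, repeats), and two-group read-level contingency
    analysis for assisted-reproduction style cohorts. Includes a
    seeded synthetic multi-tissue methylome generator with a planted
    truth channel so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
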