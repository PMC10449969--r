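Package: varburden
Title: Rare-Variant Prioritization, Gene-Set Overrepresentation and
    Summary-Statistic Burden Testing for Small Case Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a rare-variant inference chain for small case
    cohorts tested against population-scale summary controls:
    allele-ratio (allelic balance) genotype QC, a deleteriousness and
    minor-allele-frequency prioritization cascade with recurrence
    filtering, Fisher-exact gene-set overrepresentation with
    Benjamini-Hochberg FDR, and a TRAPD-style per-gene collapsing burden
    test under dominant and recessive inheritance models using only
    summary allele counts (AC/AN/nhom) on the control side. Includes a
    seeded synthetic-cohort generator with ground-truth labels so every
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
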