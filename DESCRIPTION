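Package: xciescape
Title: Allele-Specific Analysis of X-Chromosome Inactivation Escape in
    Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies escape from X-chromosome inactivation (XCI) in
    allele-resolved single-nucleus RNA-seq data from F1-hybrid mice with
    nonrandom XCI. Computes per-gene, per-cell-type escape proportions with
    autosome-based mapping-bias correction and 99% Wald confidence intervals,
    classifies escapees and their young-to-old transitions (new, increased,
    maintained, lost escape), runs pseudobulk allele-level differential
    expression between age groups with chromosome-level chi-squared
    enrichment, and ships a calibrated synthetic-data generator with planted
    ground truth so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
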