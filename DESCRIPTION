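Package: mirseed
Title: Seed-Match Target Prediction, Conservation Profiling and Inhibitor
    Design for microRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species-specific microRNA target analysis built around
    the seed-match rule: scanning 3'UTR pools for perfect matches to the
    reverse complement of miRNA nucleotides 2-7, profiling per-region
    conservation of pre-miRNA hairpin ortholog families with a built-in
    progressive aligner, scoring conserved-target overlap against reference
    target lists, gene-set (sub-network) enrichment via Mann-Whitney U and
    hypergeometric tests, antisense (LNA-style) inhibitor design and
    verification with off-target seed screening, and downstream
    efficiency-corrected qPCR quantification with one-way ANOVA and
    Student-Newman-Keuls compact-letter post-hoc grouping. A synthetic-data
    module generates every input with known ground truth for recovery and
    calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    car,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
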