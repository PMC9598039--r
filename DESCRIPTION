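Package: mirescreen
Title: Analysis of Pooled miR-E Competitive Growth Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pooled, doxycycline-inducible shRNA
    (miR-E) competitive growth screens: sample-barcode demultiplexing and
    guide counting from FASTQ, pool-based normalization with log2 transform
    and outlier trimming, replicate and control quality control, the robust
    strictly standardized mean difference effect statistic (SSMD* per
    replicate, AvSSMD* across replicates, per-gene aggregation), and
    multi-filter hit selection with cross-screen accounting. Includes a
    synthetic-screen generator (library design, clone abundances, inducible
    knockdown with configurable promoter leakiness, multinomial sequencing)
    so every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
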