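Package: njatlas
Title: Discovery of Public, Cancer-Specific Splicing Neojunctions and
    Neoantigen Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for calling recurrent ("public"),
    cancer-specific RNA splicing neojunctions from aligner splice-junction
    tables, classifying their splice type and reading-frame effect against a
    transcript annotation, computing cohort positive-sample-rate statistics,
    quantifying intron retention, measuring intratumoural (multi-region)
    conservation, and nominating HLA class I presented neoantigen candidates
    by in-silico translation, 8-11-mer tiling, proteome exclusion and
    two-scorer top-percentile intersection. Includes a seeded synthetic-cohort
    generator with machine-readable planted ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
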