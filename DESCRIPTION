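Package: enhancerstrata
Title: Chromatin-State Stratification and Nucleosome-Shape Analysis of
    TF-Bound Enhancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for summit-anchored transcription-factor
    binding sites: K-means stratification into chromatin-state groups from
    histone-mark signal (H2A.Z, H3K27ac, H3K4me1), promoter-contamination
    filtering, magnitude-independent shape clustering of local nucleosome
    signal with mirror-flip alignment, CpG methylation stratification around
    summits, GREAT-style regulatory-domain gene assignment with
    randomization-based enrichment, strand-specific meta-profiles, and a
    ground-truth synthetic-data generator for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    data.table,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
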