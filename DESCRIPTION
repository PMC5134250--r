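Package: ampmerge
Title: Merging, Stitching and Expected-Error Filtering of Paired-End Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing of paired-end Illumina amplicon sequencing data
    (e.g. 16S rRNA hypervariable regions). Merges overlapping mates with a
    context-aware scheme (best overlap by mismatch rate, quality-difference
    mismatch resolution, dataset-wide k-mer context tie-breaks), stitches
    non-overlapping mates across an N spacer with masked qualities, and
    filters amplicons by average Phred score or by maximum expected error
    as a percentage of read length (meep). Includes a per-sample quality
    statistics report and a deterministic paired-end read simulator with a
    position-dependent polynomial substitution error model for testing.
    All user-facing functions take and return tibbles so pipelines compose
    with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    stringi,
    readr,
    jsonlite,
    generics,
    ggplot2,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
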