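Package: bisulfitr
Title: Three-Letter Bisulfite Read Alignment with Chemistry Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained bisulfite sequencing alignment pipeline built
    on the three-letter (C-to-T / G-to-A) conversion strategy. Reads and
    reference are converted, mapped by strand-restricted k-mer
    seed-and-extend in a strict first tier and a permissive gapped second
    tier, then every candidate is re-evaluated on the original sequences
    under bisulfite chemistry: read-C-over-reference-T matches are
    impossible (cytosine conversion is one-directional) and are rejected,
    with optional SNP tolerance. Includes merge/deduplication to per-read
    verdicts, per-cytosine methylation calling in CpG/CHG/CHH contexts, SAM
    output with XM/XG methylation tags, color-coded alignment rendering for
    terminal and HTML, and a bisulfite read simulator (conversion failure,
    per-cycle sequencing error, all four bisulfite strands) with mappability
    evaluation, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
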