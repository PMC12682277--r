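Package: fragilerss
Title: Cryptic Recombination Signal Sequences at Chromosomal Fragile Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking structural-variant breakpoints to cryptic
    V(D)J recombination signal sequences (RSS). Provides a 12/23-RSS scanner
    with mismatch bounds and a pluggable log-odds scoring model, RAG nick-site
    prediction, single-linkage clustering of breakpoints into fragile regions
    (adjacent-gap rule), junction breakpoint and microhomology mapping for
    recombinant sequences, recombination-frequency statistics from colony
    counts with exact binomial intervals, two-gene percentile stratification
    of expression cohorts, and seeded synthetic-data generators so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
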