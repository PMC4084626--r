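Package: rsw
Title: Read-Split-Walk Detection of Short Non-Canonical Spliced Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome-wide detection of short, non-canonical spliced regions
    (such as the IRE1-alpha dependent 26 nt excision in Xbp1) from unmapped
    single-end RNA-Seq reads.  Implements the Read-Split-Walk strategy:
    unmapped reads are trimmed and split at every admissible offset, the
    halves are re-aligned to the genome with zero mismatches, and validly
    paired placements are consolidated into candidate spliced regions that
    are filtered against annotated introns, ranked by read support, and
    contrasted between case and control samples.  Ships a fully seeded
    synthetic-data generator (genome, gene models, implanted excisions,
    simulated reads) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
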