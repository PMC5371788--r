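Package: stitchkit
Title: Primer Design for Overlapping and Fusion PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates the design of primers for overlapping (fusion) PCR.
    Enumerates forward and reverse primer candidates inside user-defined 5'
    and 3' search areas of a single input sequence, filters them by GC
    content, nearest-neighbor melting temperature with monovalent-salt
    correction, GC clamp and repetitive-sequence rules, and scores
    self-complementarity, 3' complementarity, overhang complementarity,
    hairpins and cross-primer dimers with a Gibbs-free-energy-aware weighted
    match score. Fusion primers are built by prepending predefined or
    user-supplied overlap tails (fluorophore anchors, sequencing adapters),
    including a site-directed mutagenesis mode. Results are tidy tibbles:
    primer tables, compatible-pair tables, sliding-window composition
    profiles, summary statistics and a primer map, with TSV/JSON/BED writers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    utils,
    stats,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
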