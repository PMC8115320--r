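Package: phagemotifs
Title: Motif-Based Mining of Phage-Display Selection Pools from Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies antigen-specific synthetic antibody clones, including
    extremely rare ones, from paired positive/negative phage-display selection
    pools sequenced by NGS. Validates reads against a restricted-diversity
    synthetic Fab library design, removes PCR hybridization (chimera)
    artifacts with a maximum between-class inertia cutoff on L3/H3 pairing
    counts, exhaustively enumerates wildcard-constrained consensus motifs in
    each candidate's CDRs, and scores clone specificity with a
    rank-transformed Welch t-test and Cohen's d effect size. Includes a
    ground-truth simulator of selection pools and raw three-read amplicon
    data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    Biostrings,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
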