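Package: colxlink
Title: Annotation and Lysyl-Oxidase Cross-Linking Site Analysis of
    Fibrillar Collagen Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates fibrillar (clade A) collagen alpha-chains from plain
    protein sequence: the collagenous Gly-X-X' regions (minor N-terminal and
    main triple helix), the (GPP)n motif marking the C-terminal end of the
    helix, and the N- and C-telopeptide windows. Scans telopeptides for the
    X-K-X'-X'' lysyl-oxidase substrate motif and helix termini for the
    Y-K-G-Y''-Y''' acceptor motif, ranks and classifies candidate
    cross-linking lysines, checks the five-residue lysine-exclusion flank
    rule, builds K-anchored position-weight matrices with per-column
    information content (sequence-logo data), and computes the
    lysine-depletion probability statistic (1 - f_K)^N for the lysine-free
    stretches joining the helices to the cross-linking lysines. Includes a
    synthetic collagen-chain generator with planted ground truth so every
    pipeline stage is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
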