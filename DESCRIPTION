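Package: rlptools
Title: Analysis of Proximity-Editing RNA Localization Profiling Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for proximity-dependent RNA-editing experiments that map
    subcellular RNA localization with compartment-anchored deaminase reporters
    (RLP/scRLP-style designs). Calls reporter-induced A-to-G or C-to-U editing
    events from induced versus uninduced-control per-site base counts,
    quantifies per-gene editing activity (EPM, ECPM, editing efficiency) and
    its positional bias relative to poly(A) sites, computes localization
    indices against a cytoplasmic reference and clusters their temporal
    dynamics by UPGMA, performs single-cell quality control and tests
    detection-rate heterogeneity against an expression-matched shuffling null
    with a chi-square goodness-of-fit test, quantifies detained-intron ratios
    from intron/exon coverage, extracts strand-aware sequence contexts around
    editing sites, and simulates every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
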