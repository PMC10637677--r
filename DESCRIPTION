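Package: barcodegap
Title: DNA Barcoding Gap Analysis and Threshold-Based Species Identification
Version: 0.1.0
Authors@R: person("Barcodegap", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing how well a DNA barcode locus (e.g. COI or
    ITS2) discriminates species in a community sample. Computes Kimura
    2-parameter and proportion distance matrices with pairwise deletion,
    estimates species-delimitation thresholds three ways (kernel-density
    local minima, cumulative-error minimisation over a threshold grid, and
    the 95 percent intraspecific-distance rule), classifies every sequence
    with the best-close-match method (correct, incorrect, ambiguous, no id),
    summarises haplotype and nucleotide diversity, and tabulates per-species
    barcoding-gap statistics. Includes a seeded simulator of labelled
    barcode communities with controlled intra- and interspecific divergence
    for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
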