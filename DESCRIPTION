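Package: fcmap
Title: Alignment-Free Detection and Visualisation of Genomic Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds and visualises large-scale rearrangements (direct
    homologies, inversions, translocations) between pairs of DNA sequences
    without computing an alignment. A finite-context (order-k Markov) model
    is trained on a reference sequence and used to compute a per-position
    conditional information profile of a target; low-information regions of
    the target share information with the reference and are segmented,
    localised back onto the reference, classified by orientation using a
    reverse-complement model, and rendered as a paired-chromosome ideogram
    in SVG. Includes a seeded synthetic-rearrangement generator for
    validation with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2,
    withr
Config/testthat/edition: 3
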