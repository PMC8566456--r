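Package: bearkit
Title: Quantification and Design Tools for Base-Editing Splice-Donor Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gain-of-signal base-editing reporters built on an
    inactivated splice donor site, and for the amplicon deep-sequencing
    readout that accompanies them. Implements a semi-global affine-gap
    aligner with left-aligned indels, the 75 percent prefix-identity read
    filter, cut-site indel calling within a +/-2 bp window, per-position
    base-conversion matrices, specificity with a 0.05 percent indel floor,
    enrichment folds, activity-profile normalisation and correlation,
    mismatched guide-RNA panel generation, splice-donor activity
    classification with reporter-pair and PAM-placement enumeration, and a
    seeded simulator for amplicon reads and sorted cell populations so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    withr,
    generics,
    ggplot2,
    optparse,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
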