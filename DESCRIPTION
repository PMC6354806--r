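Package: srnacons
Title: Consensus Prediction of Bacterial Small RNA Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A consensus framework for predicting mRNA targets of bacterial
    small regulatory RNAs (sRNAs). Extracts sequence windows around annotated
    start codons, runs a built-in seed-and-extend RNA-RNA duplex scanner with
    shuffle-based empirical p-values, ingests prediction tables from any number
    of external algorithms as labelled channels, determines binding-site
    agreement across channels, classifies predictions against experimentally
    validated sites, assigns prioritisation ranks 1-7, and filters candidates
    by gene lists and differential-expression evidence. Includes a reverse
    search mode (an mRNA 5' UTR queried against a catalogue of sRNAs), an
    evaluation harness (sensitivity, false-positive rate, consensus-threshold
    ROC, seed-size sweeps), a synthetic-data generator with planted binding
    sites for offline validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
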