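Package: cofitval
Title: Validating Transcription-Factor Regulon Predictions with Mutant Fitness Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical validation of comparative-genomics predictions of
    transcription-factor (TF) targets using genome-wide transposon-mutant
    fitness compendia. Implements bias-corrected cofitness (Pearson
    correlation of fitness profiles), a rank-based extreme-value test
    combined with a Fisher z-transform test of the top target's cofitness,
    activator/repressor sign classification, plug-in false-discovery-rate
    estimation, randomized-target null calibration, operon inference and
    polar-effect analysis, reciprocal-best-hit propagation of predictions
    to related genomes with position-weight-matrix upstream scanning, and
    a conserved-cofitness rule for nominating candidate targets of
    uncharacterized TFs. Includes a synthetic-data generator that emulates
    a fitness compendium with known regulatory couplings, operon polar
    coupling, chromosomal-proximity correlation bias, and planted motif
    sites, so the whole method is exercisable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
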