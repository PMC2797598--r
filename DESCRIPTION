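Package: replifork
Title: Replication Fork Velocity Inference from Gene-Dosage Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers position-dependent replication fork velocity on circular
    bacterial chromosomes from genomic copy-number (gene-dosage) profiles of
    exponentially growing populations, under a steady-state model in which the
    log2 dosage of a locus declines linearly with its replication time. Includes
    piecewise-linear segment fitting and changepoint detection on log2 tracks,
    coordinate handling for rearranged (inverted/deleted) chromosomes, analysis
    of synchronized-release replication profiles (initiation fraction and fork
    front position), Luria-Delbruck fluctuation-test mutation-rate estimation by
    the P0 method, growth-rate extraction from OD600 curves, a multiplicative
    fitness null model, and competition-based relative fitness. A synthetic-data
    module generates dosage profiles, fluctuation assays, growth curves and
    competitions under known parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
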