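Package: registrylink
Title: Record Linkage Toolkit for Administrative Person Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building linked cohorts from administrative person
    registries of the kind maintained by Brazilian social and health
    information systems (CadUnico, SINASC, SIM, SINAN). Provides a synthetic
    registry generator with configurable field corruption and a gold standard
    of true pairs; preprocessing (name normalization, date standardization,
    code validation, deduplication); privacy-preserving probabilistic linkage
    via bigram Bloom-filter encodings with predicate blocking and Dice
    similarity; TF-IDF inverted-index linkage with exact, semi-exact and
    fuzzy query modes; deterministic linkage on a unique key and a two-stage
    mother-then-child strategy for birth records; and ROC-based accuracy
    assessment with cut-off calibration by the Youden index.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stringi,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
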