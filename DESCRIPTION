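Package: msconsensus
Title: Consensus Ranking and Database Boosting for In Silico MS/MS
    Compound Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combines the candidate rankings produced by several in silico
    MS/MS fragmentation tools into a single consensus ranking using a
    two-level voting model: a primary vote count and a secondary
    sensitivity-weighted rank sum, with per-tool sensitivity weights
    calibrated on a training set at a chosen top-k. Candidate structures
    can additionally be boosted by presence in compound databases (with
    extra emphasis for environmentally relevant databases) and by spectral
    library matches gated at a 0-999 dot-product threshold. Includes MGF
    and MSP peak-list readers, ChemSpider-style candidate-list handling
    keyed on the first block of the InChIKey, non-fragmentation baseline
    rankers, a top-k accuracy evaluation harness with combination sweeps,
    and a synthetic-data generator for benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
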