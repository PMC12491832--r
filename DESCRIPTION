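Package: batphen
Title: Individual-Level Hibernation Phenology from RFID Detection Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct individual hibernation phenology of bats
    from raw two-reader RFID gate-detection logs: directed gate-pass
    building with noon-to-noon "bat days" and July-to-June "bat years",
    extraction of the longest hibernation period per individual and winter,
    validation of the extraction against single-reader reanalysis and final
    departure dates, and linear mixed-model estimation of per-class year
    trends and temperature effects on hibernation start, end and duration.
    Includes a synthetic detection-stream simulator with known ground truth
    for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    emmeans,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
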