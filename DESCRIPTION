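Package: apcr
Title: Detection of Attempted Prey Captures from Head-Mounted Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting individual attempted prey captures (APC) in
    diving marine predators from head-mounted tri-axial accelerometers, and for
    validating the detector against animal-borne video annotations. Provides
    sensor time-series input/output and alignment, dive segmentation from
    time-depth records (zero-offset correction, dive finding, phase splitting),
    a moving-variance peak detector on high-pass-filtered acceleration,
    interval-based matching of detections to annotated events with full
    confusion accounting (TP/FP/FN and dive-level TN), detection/false-positive
    rate/precision error metrics with per-animal aggregation, random holdout
    grid-search optimisation of the detector's variance threshold and minimum
    peak interval, and a synthetic deployment generator that emulates benthic
    foraging dives with ground-truth annotations so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
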