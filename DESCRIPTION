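Package: bapair
Title: Automated Broncho-Arterial Pair Detection and Ratio Measurement in Lung CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects broncho-arterial (BA) pairs on axial lung CT slices and
    measures broncho-arterial ratios, the radiological criterion for
    bronchiectasis. The pipeline segments the lung fields, removes
    low-intensity clutter by histogram analysis, screens bright connected
    components with four roundness conditions to find candidate pulmonary
    arteries, locates adjacent ring-shaped bronchi by hole filling, matches
    bronchus and artery into discrete pairs, and measures four diameters and
    the pixel areas of each member to derive diameter and area BA ratios.
    Includes a synthetic phantom generator with ground truth so that every
    stage can be validated without patient data, plus a command-line
    interface for batch processing of PNG or DICOM slice stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
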