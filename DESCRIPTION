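Package: bilatgait
Title: Bilateral Gait Trend Analysis from Body-Worn Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based analysis of day-long tri-axial accelerometer recordings
    from hemiparetic patients wearing thigh and upper-arm sensors on both body
    sides. Extracts walking segments with a threshold rule on 1-second window
    features of the non-affected thigh, segments bilateral strides with
    hill-climb peak detection and an alternating verification algorithm,
    computes per-day movement parameters (stride count, stride duration,
    cadence, arm sway) for the affected and non-affected sides, and fits
    per-side linear recovery trends whose extrapolated intersection - the
    convergence point - summarises inter-limb similarity over rehabilitation.
    Includes a seeded synthetic-recording generator with ground truth for
    validation, and the published truth-table and manual-reference fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
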