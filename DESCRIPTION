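Package: finchorus
Title: Detection and Population Discrimination of Fin Whale Calls in
    Long-Term Passive Acoustic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based detection of fin whale 20-Hz pulses and of the
    low-frequency (17-25 Hz) and high-frequency (84-87 Hz, 96-100 Hz) choruses
    in long-term single-channel recordings, with daily acoustic-presence
    aggregation, peak-frequency discrimination of the 86-Hz versus 99-Hz
    song components, and transmission-loss based attribution of detected
    pulses to a radius around the recorder. Includes a synthetic-scene
    generator with ground-truth annotations so the full pipeline can be
    exercised and calibrated without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
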