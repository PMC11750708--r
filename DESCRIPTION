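Package: fingerbci
Title: Simulation and Analysis Stack for Finger-Level Intracortical Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating velocity decoders for
    finger-level intracortical brain-computer interfaces entirely in
    software. Provides a synthetic multichannel spike-band-power population
    with known velocity tuning, virtual-finger target-acquisition tasks
    (open-loop and closed-loop, 2 and 4 degrees of freedom), a temporally
    convolved feed-forward neural-network velocity decoder with
    recalibrated feedback intention-trained (ReFIT) updating, online
    performance metrics (acquisition time, path efficiency, Fitts-law
    throughput), participation-ratio dimensionality, a directional
    signal-to-noise ratio (dSNR) pipeline with channel-count scaling-law
    fits, and a kinematic quadcopter control layer driven by decoded
    finger positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
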