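Package: pkeyesim
Title: Digital Twin of a Real-Time Ocular Drug-Delivery Monitoring Platform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of an in vitro human-eye (PK-Eye) testing
    platform: porous-membrane pressure-flow hydraulics under the
    Weissberg-Sampson-Poiseuille approximation with effective pore-radius
    fitting, pressure-driven parallel flow networks with a circadian aqueous
    flow program and leak/blockage quality-control detection, well-mixed
    compartmental intraocular clearance simulation with log-linear half-life
    estimation, eye-movement trajectory and telemetry synthesis (smooth
    pursuit, saccades, micro-saccades), and a valve-multiplexed virtual
    fluorescence concentration probe with calibration and gapped-profile
    reconstruction. All results are tidy tibbles with broom-style tidiers and
    ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
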