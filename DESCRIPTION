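Package: gaitstep
Title: Step Detection, Evaluation and Simulation for Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects steps in recordings from body-worn inertial measurement
    units (IMUs) using five classical algorithms: local-maximum peak detection
    with an adaptive rolling-threshold, hysteresis zero-crossing, short-time
    Fourier transform cadence estimation, two-phase adaptive amplitude
    thresholding, and a stance-phase (SHOE-style) accelerometer/gyroscope
    fusion detector. Includes the shared preprocessing chain (vector
    magnitude, median gravity compensation, Savitzky-Golay smoothing),
    tolerance-window matching with precision/recall/F1 scoring, a clinical
    plausibility screen with bilateral left/right consistency checks, a
    seeded synthetic gait-signal simulator with ground-truth step times
    (walking, jogging, stairs, Timed Up and Go, stationary), CSV readers and
    writers with a column-mapping interpreter for heterogeneous sensor
    dialects, and a command-line interface for batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
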