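Package: ripwob
Title: Work-of-Breathing Indices from Respiratory Inductance Plethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of two-channel respiratory inductance plethysmography
    (RIP) recordings from rib-cage and abdomen bands. Computes the classical
    work-of-breathing indices on sliding analysis windows: thoracoabdominal
    phase angle, labored breathing index (LBI), and percent rib cage, plus an
    FFT-based breaths-per-minute estimate. Summarises cohorts as mean and
    standard-error tables, histograms and percent-in-range statistics, and
    classifies breathing synchrony against configurable thresholds. Includes
    a seeded synthetic thoracoabdominal-motion generator with known ground
    truth (phase lag, amplitude ratio, breathing rate) for end-to-end
    verification, CSV/JSON input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
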