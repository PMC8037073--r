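Package: ecgischemia
Title: Myocardial Ischemia Detection from Multi-Lead ECG via Choi-Williams
    Time-Frequency Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated detection of myocardial ischemia from multi-lead,
    long-interval electrocardiograms.  Implements FIR-based signal
    conditioning, one-minute segmentation, the discrete Choi-Williams
    time-frequency distribution with positive-part truncation, ST-band
    (11-14 Hz) and PR-band (5-8.5 Hz) mean-power feature extraction, and a
    per-lead one-vs-one multi-class support vector machine with radial
    basis kernel and multi-lead decision fusion.  Includes a synthetic
    multi-lead ECG generator with controllable ischemic morphology and
    realistic noise, plus readers and writers for CSV and WFDB-style
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    MASS,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
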