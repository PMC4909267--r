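Package: neoapnea
Title: Detection and Crossover Analysis of Neonatal Cardiorespiratory Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scoring apnea of prematurity and its cardiovascular
    sequelae from multichannel NICU recordings. Detects breathing pauses from
    respiratory effort, intermittent-hypoxia episodes from pulse-oximetry SpO2
    at nested thresholds, and bradycardia episodes from heart rate or ECG;
    aggregates events over 6-hour stimulation ON/OFF blocks of a within-subject
    crossover design; and reproduces the paired ln(x+1) t-test analysis with
    raw-scale mean differences and per-subject percent change. A synthetic-data
    module generates physiologically structured recordings (periodic breathing,
    apneas with lagged desaturation and bradycardia responses) and cohort
    summary tables with a configurable stimulation effect, so every stage is
    testable without clinical data. Reads and writes EDF and per-channel CSV
    bundles, event CSVs, and cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    readxl,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
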