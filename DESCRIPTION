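Package: penmetrics
Title: Stroke-Level Handwriting Metrics for Pen-Tablet Dictation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts raw digitizer pen-sample streams (timestamp, x, y,
    pressure) from handwriting-to-dictation experiments into character-,
    radical-, and stroke-level writing metrics (latency, duration, trace
    length, pen pressure, inter-unit distance), applies response coding and
    outlier exclusion rules, aggregates trials to item-level norms, and runs
    the associated statistical battery: split-half reliability with
    Spearman-Brown correction, inter-rater intraclass correlation,
    collinearity screening by stepwise variance inflation factors, multiple
    regression with Benjamini-Hochberg false-discovery-rate correction, and
    cross-level interaction models. Includes a synthetic experiment generator
    with configurable ground-truth effects and penscript/per-stroke
    diagnostic rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
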