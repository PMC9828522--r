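Package: smiledetect
Title: Episode-Wise Detection and Quantification of Smiles from Facial
    Action Unit Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects discrete smile episodes in facial action unit (AU)
    intensity time series, such as those produced by automated facial
    behaviour analysis toolkits. A frame is classified as smiling when both
    the cheek raiser (AU6, the Duchenne marker of genuineness) and the lip
    corner puller (AU12, smile intensity) exceed user-set thresholds;
    sub-threshold gaps shorter than a stand-by window are merged into a
    single episode. Each episode is quantified by onset, duration, mean
    AU6/AU12 activation and percentage tooth show (AU25), and sessions by
    episodes per minute and relative smile time. The package also
    calibrates the detector against manually coded reference intervals via
    a two-threshold ROC grid with Youden-index optimisation, reports
    episode-level agreement and confounder-task false positives, and ships
    a synthetic session generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
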