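Package: thermark
Title: Detection and Classification of Rodent Scent Marks in Thermal Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic detection and classification of mouse urine
    and fecal depositions from overhead radiometric thermal video of social
    behavior experiments. Provides radiometric calibration (blackbody offset
    and fixed-pattern non-uniformity correction), a heuristic hot-blob
    preliminary detector based on background modelling with mouse inpainting
    and cooldown screening, a trainable patch-sequence classifier that labels
    each candidate as urine, feces or background, tolerance-based accuracy
    evaluation against manually tagged events, deposition-dynamics summaries
    (per-minute rates and areas, stage windows, side attribution), and a
    synthetic thermal-session simulator with exact ground truth for testing
    the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    png,
    readr,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
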