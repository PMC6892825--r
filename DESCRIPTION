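Package: microstatr
Title: EEG Microstate Segmentation, Back-Fitting and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for resting-state EEG microstate
    analysis: deterministic preprocessing (zero-phase FIR filtering, common
    average reference, epoch screening with spherical-spline channel
    interpolation), global-field-power peak extraction, topographic
    atomize-and-agglomerate hierarchical clustering (TAAHC) of pooled peak
    topographies into K global maps, polarity-invariant back-fitting with
    temporal smoothing, microstate features (duration, occurrence, coverage,
    global explained variance), transition-syntax permutation testing, and
    covariate-adjusted group inference. Includes a synthetic resting-state
    EEG cohort generator with planted microstate structure so every stage is
    verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
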