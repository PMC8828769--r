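Package: sonopipe
Title: Analysis Pipeline for Sonogenetic Calcium-Imaging, EMG and Sequence Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ultrasound neuromodulation ("sonogenetics")
    experiments end to end: simulation of ground-truthed two-channel
    calcium-imaging movies, EMG recordings and Bernoulli screen datasets;
    ROI segmentation of the transfection-marker channel (Gaussian filter,
    background subtraction, Otsu thresholding, distance-transform watershed);
    dF/F normalisation with fixed-threshold responder calling and 63%
    rise/width kinetics; a random-intercept Bernoulli logistic screen
    statistic with Tukey-adjusted pairwise odds ratios; envelope-based EMG
    burst detection under a stimulus-artifact exclusion rule; protein
    consensus/percent-identity and fuzzy CRAC/CARC motif scanning with
    construct coordinate arithmetic; and ultrasound focal-dimension,
    attenuation and mechanical-index calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    lme4,
    mvtnorm,
    generics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
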