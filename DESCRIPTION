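Package: timebisect
Title: Temporal-Bisection Psychophysics with Synthetic EEG and ERP Feature Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for auditory temporal-bisection
    experiments with concurrent EEG. Encodes ensemble-context designs
    (skewed stimulus spacing and asymmetric sampling frequency), generates
    synthetic behavioral responses and frontocentral epoch waveforms with
    known ground truth, fits logistic psychometric functions by maximum
    likelihood to derive the point of subjective equality (PSE) and just
    noticeable difference (JND), extracts contingent-negative-variation
    (CNV) climbing rates, peak and mean amplitudes, offset P2 and late
    positive component (LPCt) measures, and crossing latencies from
    condition-averaged epochs, and runs group-level inference (paired
    t-tests with JZS Bayes factors, random-intercept linear mixed models
    with Kenward-Roger or Satterthwaite p-values, Pearson correlations).
    A pipeline driver chains design expansion, simulation, fitting,
    feature extraction and statistics into reproducible seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    pbkrtest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
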