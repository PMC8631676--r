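Package: ecglvh
Title: Electrocardiographic Detection of Echocardiographic Left Ventricular Hypertrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting echocardiographic left ventricular
    hypertrophy (LVH) from resting 12-lead ECG measurements. Implements the
    CHCM decision-tree criterion (T-wave voltage in lead I, peak-to-peak QRS
    amplitude in aVL and aVF) together with the classical comparator criteria
    (Sokolow-Lyon aVL, Cornell, Dalfo, voltage-duration-product Cornell,
    Romhilt-Estes point score), echocardiographic ground-truth quantification
    (Devereux LV mass, Mosteller body surface area, LV mass index, relative
    wall thickness, geometry and severity staging), a cost-sensitive
    entropy-based decision-tree inducer with pessimistic global pruning, exact
    diagnostic-performance evaluation (sensitivity, specificity, predictive
    values, Clopper-Pearson and Wilson intervals, prevalence algebra), and a
    seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
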