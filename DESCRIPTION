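Package: pedocluster
Title: Cluster-Based Permutation Mapping of Plantar Pressure During Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sensor-grid plantar pressure recordings of
    barefoot walking: stance-phase segmentation, landmark-based spatial
    standardization of footprints, extraction of basic gait, pressure and
    M-shape temporal parameters, scalar two-group statistics (Welch t,
    pooled-SD Cohen's d, confidence intervals, covariate-adjusted effects
    with variance inflation factors), and spatiotemporal cluster-based
    permutation inference with max-statistic family-wise error control on
    2D pressure maps and 1D stance time series. Includes a synthetic
    plantar-pressure cohort generator with analytically known ground truth
    for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    pracma,
    car
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
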