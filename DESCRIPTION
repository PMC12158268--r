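Package: halochrom
Title: Response-Time Analysis and Formulation Optimization for Halochromic pH-Sensor Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing colorimetric time series from halochromic
    (pH-indicating) polymer sensor films and for optimizing their formulation.
    Provides synthetic generators for color-kinetics time series and
    formulation/response datasets, color-space feature extraction (RGB, CIELAB,
    HSV, YCbCr), gradient-based stabilization-time detection of the pH response,
    feature selection by correlation-matrix PCA (Kaiser criterion) and the
    multiclass ReliefF algorithm, multigene genetic-programming symbolic
    regression of response time on dye and plasticizer concentrations, three
    bird-inspired metaheuristic minimizers (Parrot Optimizer, Pelican
    Optimization Algorithm, Secretary Bird Optimization Algorithm) together with
    a deterministic grid-refinement minimizer, and balanced two-factor ANOVA
    with replication. A pipeline orchestrator runs the full analysis
    reproducibly from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
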