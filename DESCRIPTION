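Package: seedkin
Title: Water-Dynamics Kinetics of Germinating Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for water dynamics in germinating seeds: per-seed
    mass time series are normalized by initial mass, interpolated with cubic
    splines to obtain water-uptake velocity and acceleration and their exact
    time averages, and the early imbibition phase is fitted to the spherical
    series solution of Fick's second law by Levenberg-Marquardt least squares
    to estimate the initial diffusion coefficient. Sample means carry
    percentile-bootstrap confidence intervals. Germination and seedling assay
    counts are summarized into vigor measurements (biological activity,
    seedling vigor index, seed-seedling transition yield index) and linked to
    the kinetic traits by residual-standardized Pearson correlation with
    significance screening and magnitude labels. A synthetic-data generator
    emulates the hourly weighing design of seed lots of known quality so every
    stage is testable end to end.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
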