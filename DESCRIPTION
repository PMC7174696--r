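Package: polarflux
Title: Polar Yield-Space Elementary Mode Analysis and Hybrid Cybernetic
    Modeling of Cell Culture Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for elementary flux mode (EFM) based dynamic metabolic
    modeling of batch cell cultures. Reads and validates small metabolic
    reaction networks, enumerates elementary modes with a double-description
    engine (plus an importer and constraint filter for externally computed
    sets), re-describes the convex yield solution space in polar
    (module/angle) coordinates for active-set selection (PSYA/LPSYA), and
    provides baseline selectors (CMOA objectives, simplified YSA/LYSA).
    Couples selected modes to a segregated two-population physiological
    culture model, renders exponential-phase dynamic metabolite profiles,
    simulates hybrid cybernetic models with matching-law regulation and a
    genetic-algorithm parameter fit, and searches minimal-adjustment
    perturbation paths through the polar mode cloud for metabolic
    engineering target exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
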