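Package: nicheshift
Title: Species Distribution Modelling and Niche Overlap Tests on Gridded
    Climate Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for studying climatic niche shift
    between related taxa. Fits presence-background maximum-entropy species
    distribution models restricted to linear, quadratic and product
    features, evaluates them with ROC-AUC and the True Skill Statistic,
    projects habitat suitability across climate eras, and compares taxa in
    a two-axis principal-component environmental space using
    kernel-smoothed occurrence densities, Schoener's D overlap, and
    permutation tests of niche equivalency and directional niche
    similarity. Includes a synthetic-landscape generator (spatially
    autocorrelated, cross-correlated climate layers, patchy soil masks,
    era shifts, occurrences drawn from a known suitability surface) so the
    whole chain is testable without external data, plus readers and
    writers for ESRI ASCII grids and occurrence tables.
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
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
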