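Package: mobesity
Title: Neighborhood Obesity Estimation from Mobility-Derived Diet and
    Physical Activity Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives neighborhood-level diet and physical activity measures
    (fast-food restaurant, fitness center, and nature park visit frequencies)
    from privacy-censored point-of-interest visit panels, and quantifies how
    much those measures improve census-tract obesity-prevalence estimation
    across five statistical and machine-learning models: ordinary least
    squares, geographically weighted regression, random forest, a feed-forward
    neural network, and geographical random forests. Includes a synthetic-data
    generator with known ground truth emulating censored mobility panels,
    compositional collinear demographics, and spatially autocorrelated
    outcomes; spatial diagnostics (global Moran's I, variance-inflation-factor
    elimination); tenfold cross-validated baseline-versus-test comparisons;
    and stepwise regression for redundancy analysis.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    car,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
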