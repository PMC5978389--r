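Package: oefish
Title: Observed/Expected Riverine Fish Biomonitoring from Boosted
    Regression Tree Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a reach-scale observed/expected (O/E) biotic index for
    riverine fish from presence/absence survey data. Fits one boosted
    regression tree occurrence model per species, selects the Cohen's
    Kappa-maximising presence threshold on a fixed probability grid,
    predicts species assemblages under current and reference-condition
    covariate scenarios, and computes per-reach O/E ratios together with a
    boosted-tree attribution of O/E to anthropogenic pressures and an NMDS
    ordination of species by their influential environmental variables.
    Includes a synthetic river-network generator with known species
    response functions so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    xgboost,
    yaml
Suggests:
    optparse,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
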