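Package: rangedyn
Title: Ensemble Species Distribution Models and Binary Range-Change Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ensemble habitat-suitability models for invasive species
    from presence records and environmental predictor stacks, binarizes them
    with the maximum-sensitivity-plus-specificity threshold, and quantifies
    range change between climate/land-use scenarios with the range ratio
    index (RRI), the range similarity index (RSI), and an
    expansion/contraction/stable decomposition. Includes pseudo-absence
    generation by surface range envelope, jackknife (permutation) predictor
    importance with Pearson collinearity pruning, bioclimatic variable
    computation from monthly climate series, latitude-aware cell areas,
    additive range overlays, and a virtual-species simulator so the whole
    pipeline can be exercised end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    mgcv,
    rpart,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
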