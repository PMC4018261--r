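Package: sdmbias
Title: Simulation and Correction of Sampling Bias in Presence-Only
    Species Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested framework for studying geographic sampling bias in
    presence-only species distribution models (SDMs). Generates a synthetic
    environmental landscape and a virtual species, degrades unbiased
    occurrence sets with four types of sampling bias at three intensities,
    applies five published bias-correction methods (systematic sampling,
    bias file, restricted background, environmental-space cluster
    filtering, and latitudinal split), fits a MaxEnt-style penalized
    presence/background suitability model behind a pluggable engine
    interface, and evaluates correction performance with AUC, Schoener's D
    in geographic and environmental (PCA-env) space, binary-map overlap,
    and the derived Delta correction-performance indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
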