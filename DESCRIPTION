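Package: evomorbid
Title: Evolutionary Deep Learning for Food-Contamination Morbidity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region-week surveillance data model and an eight-model
    morbidity-prediction stack for studying the effect of food contamination
    on gastrointestinal-disease morbidity. Implements multiple linear
    regression, a shallow feed-forward neural network, deep belief networks,
    deep (denoising) autoencoders, and evolutionary variants of the deep
    models trained with the water wave optimization metaheuristic, together
    with mean imputation for heavily missing contaminant-indicator tables,
    time-lagged supervised pair construction, fivefold cross-validation,
    a lag-sweep protocol, and a synthetic surveillance-data generator with
    planted lagged contamination effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
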