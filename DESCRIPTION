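Package: acobp
Title: Ant-Colony-Initialised Backpropagation Networks for Exercise-Load
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hybrid training of small feedforward regression networks for
    athlete exercise-load monitoring. An ant-colony search over a
    discretised weight space supplies initial weights that are then
    fine-tuned by backpropagation (plain or with a momentum term).
    Includes the generic ant-system optimiser with a travelling-salesman
    instantiation, a preprocessing chain (interpolation-based imputation,
    min-max normalisation, log transform, PCA feature selection,
    train/test splitting), a seeded synthetic athlete-monitoring data
    generator, trainer-comparison and per-parameter significance
    reporting, and CSV/JSON model input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
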