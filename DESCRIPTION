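Package: pairdose
Title: Hybrid Global-Local Prediction of Drug-Combination Dose-Response Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the response of a drug pair at given doses in a given
    cancer cell line by combining two complementary models: a global neural
    network trained on all available (drug, drug, dose, dose, cell line)
    measurements -- with a character-level 1D convolutional SMILES encoder,
    a fixed sinusoidal dose embedding, and a gene-expression multilayer
    perceptron -- and a local semi-supervised graph convolutional network
    trained per query on retrieved measurements that share the query's drug
    pair and cell line. A learnable aggregator fuses the two predictions and
    reduces exactly to the global model when no local information exists.
    Includes a synthetic generator for Hill-curve monotherapy and
    Bliss-independence combination surfaces with localized synergy bumps,
    scenario-based cross-validation splits (matrix completion, new
    combination, new drug, new cell line), and an ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
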