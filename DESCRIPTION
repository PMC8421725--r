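Package: nrpredict
Title: Neural Response Prediction from Artificial Network Activations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the neural predictivity of artificial
    neural networks by explicitly decoding their internal activations into
    predicted biological neural responses. Implements a small nonlinear
    decoder network with locally dense first-layer connectivity, trained by
    mean squared error with Adam-style updates and validation-based early
    stopping; a closed-form (optionally ridge-regularized) linear regression
    baseline; the NRP-error metric (mean absolute error per brain region,
    averaged across regions); hyperparameter grid search; a global magnitude
    pruning harness with sparsity sweeps; and a fully seeded synthetic data
    generator that emulates primate V4/IT recording tables so every stage is
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
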