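Package: gafuse
Title: Genetic-Algorithm Weighted Fusion of Multi-Class Classifier Probabilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines the class-probability outputs of several multi-class
    classifiers by simple or weighted averaging and selects the fusion
    weights with a genetic algorithm constrained to the probability
    simplex, using overall ensemble accuracy as the fitness. Provides
    one-vs-rest precision, recall and F1 with micro, macro and
    support-weighted aggregation, top-k accuracy, an exhaustive
    grid-search oracle for verifying the optimizer, and a calibrated
    simulator of softmax-like classifier outputs with controllable
    accuracy, sharpness and inter-model error correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, yaml
Suggests: testthat (>= 3.0.0), caret, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
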