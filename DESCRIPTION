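Package: abstainr
Title: Abstaining Binary Classification with Symmetric and Asymmetric
    Abstention Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selective prediction for binary biomedical classifiers. Given
    per-sample positive-class probabilities and ground-truth labels, the
    package finds the symmetric or asymmetric abstention interval that
    maximizes the product of the Matthews correlation coefficient (MCC) of
    the classified samples and the fraction of samples classified, and
    trichotomizes predictions into positive, negative, and rejected. It
    includes confusion counting with a reject option, 1-D and 2-D grid-search
    optimizers with Pareto-front extraction over (MCC, coverage), a
    synthetic-data generator with a closed-form population oracle, an
    end-to-end experiment pipeline with a pluggable probabilistic base
    classifier, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
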