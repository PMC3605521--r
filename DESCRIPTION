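Package: nutribalance
Title: Nutrient Balances and Compositional Data Analysis of Plant Ionomes
Version: 0.1.0
Authors@R:
    person("J.", "Demers", email = "jdemers@example.org", role = c("aut", "cre"))
Description: Log-ratio analysis of leaf tissue nutrient signatures (ionomes)
    treated as compositional data. Provides closure and filling-value handling,
    additive, centered and isometric log-ratio transforms built from sequential
    binary partitions, Aitchison distances with an explicit decomposition of the
    bias incurred by ordinary log-Euclidean distances, normality and
    scale-dependency diagnostics, robust Mahalanobis outlier screening, canonical
    discriminant analysis with confidence ellipses, a logistic-normal synthetic
    ionome generator, and a command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
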