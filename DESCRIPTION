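Package: pofkit
Title: Probability-of-Failure Analysis of Metabolic Networks from Minimal Cut Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the structural robustness of metabolic networks as a
    probability of failure (PoF): the chance that random loss-of-function
    mutations, striking each reaction at a fixed rate, include a lethal
    combination. The PoF is computed from the network's minimal cut sets
    (MCSs) by inclusion-exclusion over MCS unions, either exactly or through
    a truncated estimator with a guaranteed worst-case error bound. Includes
    binomially weighted failure frequencies, an essential-reaction closed
    form, brute-force MCS enumeration for small stoichiometric models via
    linear programming growth tests, flux-variability-based model
    consistency, linear network compression with weighted (lumped) cut sets,
    pairwise network similarity, carbon-source robustness scans, synthetic
    fixture generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
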