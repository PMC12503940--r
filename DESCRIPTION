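Package: condbias
Title: Conditional Simplicity Bias in Genotype-Phenotype Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates phenotype transition probabilities P(x -> y) under
    single-point mutations in several self-contained genotype-phenotype map
    simulators (a matrix-multiplication gene-regulation map, two-tile
    eight-colour polyomino self-assembly, the 2-D hydrophobic/polar lattice
    protein model, and an up-down time-series discretizer), computes
    conditional Lempel-Ziv complexities of the phenotype patterns, and tests
    three increasingly stringent levels of the conditional simplicity-bias
    bound P(x -> y) <= 2^(-a*K(y|x) - b): a negative rank correlation, a
    linear upper-bound decay, and a bootstrap comparison of the fitted
    upper-bound slope against the bound-model slope. Includes a null
    transition generator with tunable bias for calibration and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
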